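# Force an optimized build of the MD core; the default platform CXXFLAGS
# (appended after PKG_CXXFLAGS) would otherwise cap optimisation at -O2.
CXXFLAGS := $(CXXFLAGS) -O3 -funroll-loops
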