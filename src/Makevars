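# Forbid fused multiply-add contraction: the compiled derivative path must
# execute the same binary64 operation sequence as interpreted R arithmetic.
PKG_CXXFLAGS = -ffp-contract=off
CXX_STD = CXX17
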