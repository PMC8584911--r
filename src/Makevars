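# The training kernel is dominated by exp/log in the concrete selection
# layer; -O3 -ffast-math lets the compiler use the vectorized libm so the
# per-sample Gumbel-softmax stays cheap.
PKG_CXXFLAGS = -O3 -ffast-math -fopenmp-simd
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
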