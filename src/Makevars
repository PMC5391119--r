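# GMP lives in the same prefix as R itself (R_HOME = <prefix>/lib/R)
PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lgmpxx -lgmp
CXX_STD = CXX17
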