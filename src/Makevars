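# build with the system toolchain so the shared object resolves against
# the system C library at load time
override CXX = /usr/bin/g++ -std=gnu++17
override CXX17 = /usr/bin/g++
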