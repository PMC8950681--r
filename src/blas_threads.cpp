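// Runtime control of the BLAS thread pool. Dense training on a machine
// whose cgroup grants fewer CPUs than the hardware reports makes an
// auto-sized OpenBLAS pool thrash badly, so the package pins it
// explicitly at load time (see .onLoad).
#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// [[Rcpp::export(name = ".set_blas_threads_cpp")]]
bool set_blas_threads(int n) {
#ifndef _WIN32
  typedef void (*setter)(int);
  setter fn = reinterpret_cast<setter>(
    dlsym(RTLD_DEFAULT, "openblas_set_num_threads"));
  if (fn != nullptr) {
    fn(n);
    return true;
  }
#endif
  return false;
}
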