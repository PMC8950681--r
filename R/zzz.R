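.onLoad <- function(libname, pkgname) {
  # One BLAS thread by default: gemm-heavy training oversubscribes badly
  # when OpenBLAS sizes its pool from hardware cores it cannot actually
  # use. Override with IDPRED_BLAS_THREADS.
  n <- suppressWarnings(as.integer(Sys.getenv("IDPRED_BLAS_THREADS", "1")))
  if (!is.na(n) && n >= 1L) {
    invisible(.set_blas_threads_cpp(n))
  }
  invisible()
}
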