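# circuits and networks are deterministic given the variant, so build each
# once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_circuit <- function(variant = "MFN1") {
  cached(paste0("circ_", variant), build_mfn(variant))
}

test_network <- function(variant = "MFN1", lambda_low = 4.5e-2) {
  cached(sprintf("net_%s_%g", variant, lambda_low),
         build_network(variant, lambda_low = lambda_low,
                       circuit = test_circuit(variant)))
}

# a decoupled circuit: no internal connections, so each unit is an
# independent leaky integrator of its input
decoupled_circuit <- function(tau = c(rep(60, 4), rep(2, 4))) {
  circ <- test_circuit("MFN1")
  circ$W <- matrix(0, 8, 8)
  circ$w_ff <- c(1, 1, 0, 0, 1, 0, 1, 0)
  circ$w_fb <- 1 - circ$w_ff
  circ$I_bg <- rep(0, 8)
  circ$tau <- tau
  circ$baseline <- rep(0, 8)
  circ
}
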