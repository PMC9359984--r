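# Physical constants (CODATA 2018); SI units throughout.
.FARADAY <- 96485.33212      # C mol^-1
.GAS_R <- 8.31446261815324   # J mol^-1 K^-1
.EPS0 <- 8.8541878128e-12    # F m^-1
.AVOGADRO <- 6.02214076e23   # mol^-1

# Root-finding tolerances used by all speciation solvers.
.ABS_TOL_M <- 1e-15   # absolute, mol L^-1
.REL_TOL <- 1e-12
.MAX_ITER <- 200L

#' @keywords internal
"_PACKAGE"
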