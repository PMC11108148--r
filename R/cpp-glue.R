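# Thin wrappers around the compiled model core (src/edneg.cpp).

.edneg_rhs_cpp <- function(t, y, parms) {
  .Call("c_edneg_rhs", as.numeric(t), as.numeric(y), as.numeric(parms),
        PACKAGE = "edneguq")
}

.edneg_jac_cpp <- function(t, y, parms) {
  .Call("c_edneg_jacobian", as.numeric(t), as.numeric(y), as.numeric(parms),
        PACKAGE = "edneguq")
}

.edneg_gates_cpp <- function(phi_s, phi_d, ca_dn, x, parms) {
  .Call("c_edneg_gates", as.numeric(phi_s), as.numeric(phi_d),
        as.numeric(ca_dn), as.numeric(x), as.numeric(parms),
        PACKAGE = "edneguq")
}

.edneg_fluxes_cpp <- function(y, parms, membrane) {
  .Call("c_edneg_fluxes", as.numeric(y), as.numeric(parms),
        as.integer(membrane), PACKAGE = "edneguq")
}
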