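# Shared fixtures: the default extinction basis is deterministic, build it
# once per test run.
default_basis <- build_extinction_basis()

# Characterized isotherm parameters used as generating truth throughout.
ref_constants <- reference_binding_constants()

# Independent equilibrium oracle: solves the full conservation system
# (dye + site depletion) with stats::uniroot on the free-site concentration,
# sharing no code with solve_equilibrium().
oracle_equilibrium <- function(params, rna_bp) {
  sp <- params$sp_fraction * params$total_dye
  d_open <- params$total_dye - sp
  r_free <- 10^(params$pka_free - params$ph)
  k_mch <- params$k_micro
  k_mc <- params$k_micro * 10^(params$pka_free - params$pka_bound)
  bound_of <- function(s) {
    mc_free <- d_open / (1 + r_free + (k_mc + k_mch * r_free) * s)
    (k_mc + k_mch * r_free) * mc_free * s
  }
  s <- if (rna_bp == 0) 0 else {
    stats::uniroot(function(s) s + bound_of(s) - rna_bp,
                   lower = 0, upper = rna_bp, tol = 1e-18)$root
  }
  mc_free <- d_open / (1 + r_free + (k_mc + k_mch * r_free) * s)
  list(sp = sp, mc_free = mc_free, mch_free = r_free * mc_free,
       mc_bound = k_mc * mc_free * s, mch_bound = k_mch * r_free * mc_free * s)
}
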