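# Independent oracles shared by unit and acceptance tests.

# brute-force marginal: enumerate the death year (absorbing alive state) and
# the per-year three-state availability analytically
enum_capture <- function(y_surv, c_sb, first, phi_t, pa, pr_t, p_r_sb, M) {
  Tn <- length(y_surv)
  total <- 0
  for (death_after in first:Tn) { # alive through year `death_after`
    pz <- 1
    if (first < Tn) {
      for (t in (first + 1):Tn) {
        alive_prev <- (t - 1) <= death_after
        alive_t <- t <= death_after
        if (alive_prev) pz <- pz * (if (alive_t) phi_t[t - 1] else 1 - phi_t[t - 1])
      }
    }
    pobs <- 1
    if (first < Tn) {
      for (t in (first + 1):Tn) {
        if (t > death_after) {
          if (y_surv[t] != 0 || c_sb[t] != 0) pobs <- 0
          next
        }
        pt <- 0
        for (s_av in 1:3) {
          e <- pa[s_av, t]
          pdet <- if (s_av <= 2) pr_t[t] else 0
          e <- e * (if (y_surv[t] == 1) pdet else 1 - pdet)
          pocc <- if (s_av == 1) p_r_sb else 0
          e <- e * (if (c_sb[t] > 0 && s_av != 1) {
            0
          } else {
            pocc^c_sb[t] * (1 - pocc)^(M - c_sb[t])
          })
          pt <- pt + e
        }
        pobs <- pobs * pt
      }
    }
    total <- total + pz * pobs
  }
  log(total)
}

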