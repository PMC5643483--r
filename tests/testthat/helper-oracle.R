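# Independent brute-force formula enumerator used as the oracle for the
# pruned implementation. It carries its own atomic masses and its own filter
# arithmetic, and enumerates the complete C x H grid explicitly (precomputed
# and searched by mass window) for every N, S, P, O combination — no analytic
# hydrogen solving.

oracle_masses <- c(C = 12.0, H = 1.007825032, N = 14.003074005,
                   O = 15.994914620, S = 31.972071174, P = 30.973761998)

oracle_enumerate <- function(mass, cfg = exometab::assignment_config()) {
  em <- oracle_masses
  er <- cfg$element_ranges
  ch <- expand.grid(C = er$C[1]:er$C[2], H = er$H[1]:er$H[2],
                    KEEP.OUT.ATTRS = FALSE)
  ch$mass <- ch$C * em[["C"]] + ch$H * em[["H"]]
  ch <- ch[order(ch$mass), ]
  tol <- cfg$tolerance_ppm * 1e-6
  lo <- mass * (1 - tol)
  hi <- mass * (1 + tol)
  hits <- list()
  for (N in er$N[1]:er$N[2]) {
    for (S in er$S[1]:er$S[2]) {
      for (P in er$P[1]:er$P[2]) {
        for (O in er$O[1]:er$O[2]) {
          base <- N * em[["N"]] + S * em[["S"]] + P * em[["P"]] + O * em[["O"]]
          i1 <- findInterval(lo - base, ch$mass) + 1L
          i2 <- findInterval(hi - base, ch$mass)
          if (i2 < i1) next
          for (k in i1:i2) {
            C <- ch$C[k]
            H <- ch$H[k]
            dbe <- 1 + C - H / 2 + (N + P) / 2
            if (H / C < cfg$hc_range[1] || H / C > cfg$hc_range[2]) next
            if (O / C > cfg$oc_max) next
            if (dbe < cfg$dbe_range[1] || dbe > cfg$dbe_range[2]) next
            if (cfg$require_integer_dbe && abs(dbe - round(dbe)) > 1e-9) next
            hits[[length(hits) + 1L]] <- c(C = C, H = H, N = N, O = O,
                                           S = S, P = P)
          }
        }
      }
    }
  }
  vapply(hits, oracle_format, "")
}

# Hill-notation string built independently of the package formatter
oracle_format <- function(counts) {
  ord <- c("C", "H", "N", "O", "P", "S") # C, H, then alphabetical
  parts <- vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, "")
  paste0(parts, collapse = "")
}

# hand-sum monoisotopic mass oracle used to freeze expected masses
oracle_mass <- function(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0) {
  sum(c(C, H, N, O, S, P) * oracle_masses[c("C", "H", "N", "O", "S", "P")])
}

# convenience: a small plausible CHNOS formula drawn with the generator's
# integer-DBE construction, for property tests
random_plausible_formula <- function() {
  repeat {
    C <- sample(5:25, 1)
    N <- sample(0:3, 1)
    O <- sample(0:12, 1)
    S <- sample(0:1, 1)
    dbe <- sample(0:10, 1)
    H <- 2 * (1 + C - dbe) + N
    if (H >= 1 && H / C >= 0.3 && H / C <= 2.5 && (C == 0 || O / C <= 1.2)) {
      return(oracle_format(c(C = C, H = H, N = N, O = O, S = S, P = 0)))
    }
  }
}
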