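## Independent brute-force oracle for formula enumeration: an exhaustive
## nested-loop sweep of the CHNOSP lattice (innermost hydrogen loop
## vectorized), with no knowledge of the candidate-generation shortcut used
## by enumerate_formulas(). The full lattice up to `max_mass` is built once
## and cached for the session.

.oracle_env <- new.env(parent = emptyenv())

oracle_formula_library <- function(max_mass = 701) {
  key <- paste0("lib_", max_mass)
  if (!is.null(.oracle_env[[key]])) return(.oracle_env[[key]])
  em <- c(c = 12, h = 1.00782503207, n = 14.0030740048,
          o = 15.9949146196, s = 31.97207100, p = 30.97376163)
  blocks <- expand.grid(n = 0:4, s = 0:2, p = 0:1)
  cs <- hs <- ns <- os <- ss <- ps <- ms <- vector("list", 0)
  for (b in seq_len(nrow(blocks))) {
    nb <- blocks$n[b]; sb <- blocks$s[b]; pb <- blocks$p[b]
    het <- nb * em["n"] + sb * em["s"] + pb * em["p"]
    if (het > max_mass) next
    for (cc in seq_len(floor((max_mass - het) / em["c"]))) {
      o_max <- floor((max_mass - het - cc * em["c"]) / em["o"])
      if (o_max < 0) next
      for (oo in 0:o_max) {
        base <- cc * em["c"] + oo * em["o"] + het
        h_max <- min(2 * cc + 2 + nb + pb, floor((max_mass - base) / em["h"]))
        if (h_max < 0) next
        hh <- 0:h_max
        k <- length(cs) + 1L
        cs[[k]] <- rep.int(cc, length(hh)); hs[[k]] <- hh
        ns[[k]] <- rep.int(nb, length(hh)); os[[k]] <- rep.int(oo, length(hh))
        ss[[k]] <- rep.int(sb, length(hh)); ps[[k]] <- rep.int(pb, length(hh))
        ms[[k]] <- base + hh * em["h"]
      }
    }
  }
  lib <- data.frame(c = unlist(cs), h = unlist(hs), n = unlist(ns),
                    o = unlist(os), s = unlist(ss), p = unlist(ps),
                    mass = unlist(ms))
  lib <- lib[check_rules(lib)$pass, , drop = FALSE]
  .oracle_env[[key]] <- lib
  lib
}

oracle_enumerate <- function(neutral_mass, tol_ppm, max_mass = 701) {
  lib <- oracle_formula_library(max_mass)
  hit <- abs(lib$mass - neutral_mass) / neutral_mass * 1e6 <= tol_ppm
  lib[hit, , drop = FALSE]
}

formula_key <- function(f) sort(paste(f$c, f$h, f$n, f$o, f$s, f$p))
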