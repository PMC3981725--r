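## Monoisotopic element masses (Da), most abundant isotope. 12C is exactly 12
## by definition of the unified atomic mass unit.
.element_mass <- c(
  c = 12,
  h = 1.00782503207,
  n = 14.0030740048,
  o = 15.9949146196,
  s = 31.97207100,
  p = 30.97376163
)

#' Mass of a proton in Da, used for the [M-H]- ion convention
#' @export
PROTON_MASS <- 1.00727646

.formula_cols <- c("c", "h", "n", "o", "s", "p")

## Coerce a formula specification (data.frame of element-count columns, or a
## single named vector) to an integer data.frame with columns c,h,n,o,s,p.
.as_formula_df <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) x <- as.data.frame(as.list(x))
  if (!is.data.frame(x)) stop("formulas must be a data.frame or named numeric vector")
  for (el in .formula_cols) if (is.null(x[[el]])) x[[el]] <- 0L
  out <- x[.formula_cols]
  bad <- vapply(out, function(v) any(v < 0 | v != round(v)), logical(1))
  if (any(bad)) stop("element counts must be non-negative integers: ",
                     paste(.formula_cols[bad], collapse = ", "))
  out[] <- lapply(out, as.integer)
  out
}

#' Neutral monoisotopic mass of elemental formulas
#'
#' Computes the neutral monoisotopic mass (Da) of CHNOSP formulas as the sum
#' of element counts times monoisotopic element masses.
#'
#' @param formulas data.frame with integer columns `c`, `h`, `n`, `o`, `s`,
#'   `p` (missing columns are taken as 0), or a single named numeric vector.
#' @return numeric vector of neutral masses in Da.
#' @examples
#' formula_mass(c(c = 6, h = 12, o = 6))  # glucose, 180.0634 Da
#' @export
formula_mass <- function(formulas) {
  f <- .as_formula_df(formulas)
  as.numeric(as.matrix(f) %*% .element_mass[.formula_cols])
}

#' Convert measured m/z to neutral mass
#'
#' Negative electrospray ionization of DOM produces singly deprotonated
#' [M-H]- ions; the neutral mass is the measured m/z plus one proton mass.
#' Only charge -1 is supported (multiply charged ions are not considered).
#'
#' @param mz numeric vector of measured mass-to-charge ratios.
#' @param charge ion charge; must be -1.
#' @return numeric vector of neutral masses (Da).
#' @export
neutral_mass_from_mz <- function(mz, charge = -1L) {
  if (length(charge) != 1 || charge != -1L)
    stop("unsupported charge: only singly deprotonated [M-H]- ions (charge = -1) are handled")
  mz + PROTON_MASS
}

#' Ion m/z of a neutral mass under the [M-H]- convention
#' @param neutral_mass numeric vector of neutral masses (Da).
#' @return numeric vector of ion m/z values.
#' @export
mz_from_neutral_mass <- function(neutral_mass) neutral_mass - PROTON_MASS

#' Double bond equivalents of formulas
#'
#' DBE = (2C + 2 + N + P - H)/2, the rings-plus-double-bonds count of an
#' even-electron neutral molecule.
#'
#' @inheritParams formula_mass
#' @return numeric vector of DBE values (may be half-integer for formulas
#'   violating the valence parity rule).
#' @export
formula_dbe <- function(formulas) {
  f <- .as_formula_df(formulas)
  (2 * f$c + 2 + f$n + f$p - f$h) / 2
}

#' Van Krevelen coordinates of formulas
#'
#' @inheritParams formula_mass
#' @return data.frame with columns `oc` (O/C) and `hc` (H/C).
#' @export
van_krevelen_coords <- function(formulas) {
  f <- .as_formula_df(formulas)
  if (any(f$c < 1)) stop("van Krevelen coordinates require at least one carbon")
  data.frame(oc = f$o / f$c, hc = f$h / f$c)
}

#' Compact Hill-style formula strings (C, H, then alphabetical)
#' @inheritParams formula_mass
#' @return character vector like "C6H12O6".
#' @export
formula_string <- function(formulas) {
  f <- .as_formula_df(formulas)
  part <- function(sym, cnt) ifelse(cnt == 0L, "", paste0(sym, cnt))
  paste0(part("C", f$c), part("H", f$h), part("N", f$n), part("O", f$o),
         part("P", f$p), part("S", f$s))
}

#' Molecular-formula assignment rules
#'
#' Constructs the rule set used to screen candidate elemental compositions.
#' Defaults follow common DOM FT-ICR-MS practice: element caps O<=C, N<O,
#' N<=4, S<=2, P<=1; at most one of N, S, P nonzero (heteroatom classes are
#' not combined); hydrogen within 0 <= H <= 2C+2+N+P; DBE a non-negative
#' integer (even-electron neutrals); neutral mass within the instrument
#' window of 150-1800 Da.
#'
#' @param tol_ppm assignment tolerance in ppm (default 0.5).
#' @param mass_range numeric length-2, allowed neutral mass window in Da.
#' @param max_n,max_s,max_p element caps.
#' @param n_strictly_less_o if TRUE (default) enforce N < O literally, which
#'   excludes oxygen-free formulas; if FALSE relax to N <= O.
#' @param heteroatom_exclusive if TRUE (default) at most one of N, S, P may
#'   be nonzero.
#' @param hc_range optional numeric length-2 H/C screen (default NULL = off).
#' @return object of class `assignment_rules`.
#' @export
assignment_rules <- function(tol_ppm = 0.5, mass_range = c(150, 1800),
                             max_n = 4L, max_s = 2L, max_p = 1L,
                             n_strictly_less_o = TRUE,
                             heteroatom_exclusive = TRUE,
                             hc_range = NULL) {
  stopifnot(tol_ppm >= 0, length(mass_range) == 2, mass_range[1] < mass_range[2],
            max_n >= 0, max_s >= 0, max_p >= 0)
  structure(list(tol_ppm = tol_ppm, mass_range = as.numeric(mass_range),
                 max_n = as.integer(max_n), max_s = as.integer(max_s),
                 max_p = as.integer(max_p),
                 n_strictly_less_o = isTRUE(n_strictly_less_o),
                 heteroatom_exclusive = isTRUE(heteroatom_exclusive),
                 hc_range = hc_range),
            class = "assignment_rules")
}

#' Check formulas against assignment rules
#'
#' Evaluates every rule and reports all violations, not just the first.
#'
#' @inheritParams formula_mass
#' @param rules an [assignment_rules()] object.
#' @return data.frame with logical `pass` and character `violations`
#'   (comma-separated rule labels, "" when passing), one row per formula.
#' @export
check_rules <- function(formulas, rules = assignment_rules()) {
  f <- .as_formula_df(formulas)
  viol <- matrix(FALSE, nrow(f), 0)
  add <- function(viol, label, bad) {
    m <- cbind(viol, bad); colnames(m)[ncol(m)] <- label; m
  }
  viol <- add(viol, "C>=1", f$c < 1)
  viol <- add(viol, "O<=C", f$o > f$c)
  if (rules$n_strictly_less_o) {
    viol <- add(viol, "N<O", f$n >= f$o)
  } else {
    viol <- add(viol, "N<=O", f$n > f$o)
  }
  viol <- add(viol, paste0("N<=", rules$max_n), f$n > rules$max_n)
  viol <- add(viol, paste0("S<=", rules$max_s), f$s > rules$max_s)
  viol <- add(viol, paste0("P<=", rules$max_p), f$p > rules$max_p)
  if (rules$heteroatom_exclusive)
    viol <- add(viol, "NSP-exclusive", (f$n > 0) + (f$s > 0) + (f$p > 0) > 1)
  viol <- add(viol, "H-range", f$h < 0 | f$h > 2 * f$c + 2 + f$n + f$p)
  dbe <- (2 * f$c + 2 + f$n + f$p - f$h) / 2
  viol <- add(viol, "DBE", dbe < 0 | dbe != floor(dbe))
  if (!is.null(rules$hc_range)) {
    hc <- f$h / pmax(f$c, 1)
    viol <- add(viol, "H/C-range", hc < rules$hc_range[1] | hc > rules$hc_range[2])
  }
  violations <- apply(viol, 1, function(v) paste(colnames(viol)[v], collapse = ","))
  data.frame(pass = !apply(viol, 1, any), violations = violations,
             stringsAsFactors = FALSE)
}

## Heteroatom blocks compatible with the exclusivity rule: (n, s, p) with at
## most one class nonzero. Without exclusivity, the full cross product.
.heteroatom_blocks <- function(rules) {
  if (rules$heteroatom_exclusive) {
    blocks <- rbind(c(0, 0, 0),
                    if (rules$max_n > 0) cbind(seq_len(rules$max_n), 0, 0),
                    if (rules$max_s > 0) cbind(0, seq_len(rules$max_s), 0),
                    if (rules$max_p > 0) cbind(0, 0, seq_len(rules$max_p)))
  } else {
    blocks <- as.matrix(expand.grid(n = 0:rules$max_n, s = 0:rules$max_s,
                                    p = 0:rules$max_p))
  }
  colnames(blocks) <- c("n", "s", "p")
  blocks
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Exhaustive elemental-composition decomposition over the constrained
#' CHNOSP integer lattice. For each allowed heteroatom block the search
#' loops carbon and oxygen counts; hydrogen is solved by rounding
#' (mass - heavy-atom mass)/m_H, which is exhaustive because the tolerance
#' window (ppm scale) is far narrower than one hydrogen mass. Candidates are
#' kept iff the recomputed exact mass is within `rules$tol_ppm` of the target
#' and every rule in `rules` passes.
#'
#' @param neutral_mass single neutral mass in Da; must lie inside
#'   `rules$mass_range`.
#' @param rules an [assignment_rules()] object.
#' @return data.frame of candidates sorted by |ppm error|, with columns
#'   `c,h,n,o,s,p,mass,ppm_error,dbe,oc,hc`. Zero rows when no composition
#'   matches.
#' @export
enumerate_formulas <- function(neutral_mass, rules = assignment_rules()) {
  stopifnot(length(neutral_mass) == 1, is.finite(neutral_mass))
  if (neutral_mass < rules$mass_range[1] || neutral_mass > rules$mass_range[2])
    stop(sprintf("neutral mass %.4f Da outside allowed range [%g, %g] Da",
                 neutral_mass, rules$mass_range[1], rules$mass_range[2]))
  m <- neutral_mass
  tol_da <- m * rules$tol_ppm * 1e-6
  em <- .element_mass
  blocks <- .heteroatom_blocks(rules)
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    nb <- unname(blocks[b, "n"]); sb <- unname(blocks[b, "s"])
    pb <- unname(blocks[b, "p"])
    het_mass <- nb * em[["n"]] + sb * em[["s"]] + pb * em[["p"]]
    c_max <- floor((m + tol_da - het_mass) / em[["c"]])
    if (c_max < 1) next
    cc <- seq_len(c_max)
    o_min <- if (rules$n_strictly_less_o) nb + 1L else nb
    ## all (c, o) pairs with o_min <= o <= c
    n_o <- pmax(cc - o_min + 1L, 0L)
    keep <- n_o > 0L
    if (!any(keep)) next
    cv <- rep(cc[keep], n_o[keep])
    ov <- unlist(lapply(cc[keep], function(ci) seq.int(o_min, ci)), use.names = FALSE)
    heavy <- cv * em[["c"]] + ov * em[["o"]] + het_mass
    hv <- round((m - heavy) / em[["h"]])
    ok <- hv >= 0 & hv <= 2 * cv + 2 + nb + pb
    if (!any(ok)) next
    cv <- cv[ok]; ov <- ov[ok]; hv <- hv[ok]
    mass <- heavy[ok] + hv * em[["h"]]
    ppm <- (mass - m) / m * 1e6
    ok2 <- abs(ppm) <= rules$tol_ppm
    ## parity/DBE: h must leave (2c+2+n+p-h) even and non-negative
    dbe <- (2 * cv + 2 + nb + pb - hv) / 2
    ok2 <- ok2 & dbe >= 0 & dbe == floor(dbe)
    if (!is.null(rules$hc_range))
      ok2 <- ok2 & hv / cv >= rules$hc_range[1] & hv / cv <= rules$hc_range[2]
    if (!any(ok2)) next
    out[[b]] <- data.frame(c = cv[ok2], h = as.integer(hv[ok2]), n = nb,
                           o = ov[ok2], s = sb, p = pb,
                           mass = mass[ok2], ppm_error = ppm[ok2],
                           dbe = dbe[ok2])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(c = integer(), h = integer(), n = integer(),
                      o = integer(), s = integer(), p = integer(),
                      mass = numeric(), ppm_error = numeric(), dbe = numeric())
  res <- res[order(abs(res$ppm_error)), , drop = FALSE]
  rownames(res) <- NULL
  vk <- if (nrow(res)) van_krevelen_coords(res) else data.frame(oc = numeric(), hc = numeric())
  cbind(res, vk)
}

#' Assign molecular formulas to a calibrated peak list
#'
#' Converts each m/z to a neutral mass ([M-H]- convention), enumerates
#' candidate formulas under `rules`, and classifies each peak as `unique`
#' (exactly one candidate), `ambiguous` (several; never silently resolved)
#' or `unassigned` (none, or outside the mass window).
#'
#' @param peaks data.frame with at least a numeric `mz` column.
#' @param rules an [assignment_rules()] object.
#' @return list of class `formula_assignment` with elements
#'   `assignments` (data.frame: mz, neutral_mass, status, n_candidates and,
#'   for unique assignments, the formula columns, ppm_error, dbe, oc, hc),
#'   `candidates` (list of candidate data.frames, one per peak) and
#'   `summary` (n_peaks, n_unique, n_ambiguous, n_unassigned).
#' @export
assign_peaklist <- function(peaks, rules = assignment_rules()) {
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  n <- nrow(peaks)
  neutral <- neutral_mass_from_mz(peaks$mz)
  cand <- vector("list", n)
  status <- character(n)
  ncand <- integer(n)
  fcols <- data.frame(c = rep(NA_integer_, n), h = rep(NA_integer_, n),
                      n = rep(NA_integer_, n), o = rep(NA_integer_, n),
                      s = rep(NA_integer_, n), p = rep(NA_integer_, n),
                      ppm_error = rep(NA_real_, n), dbe = rep(NA_real_, n),
                      oc = rep(NA_real_, n), hc = rep(NA_real_, n))
  in_range <- neutral >= rules$mass_range[1] & neutral <= rules$mass_range[2]
  for (i in seq_len(n)) {
    if (!in_range[i]) {
      cand[[i]] <- NULL; status[i] <- "unassigned"; ncand[i] <- 0L
      next
    }
    ci <- enumerate_formulas(neutral[i], rules)
    cand[[i]] <- ci
    ncand[i] <- nrow(ci)
    status[i] <- if (nrow(ci) == 0) "unassigned"
                 else if (nrow(ci) == 1) "unique" else "ambiguous"
    if (nrow(ci) == 1)
      fcols[i, ] <- ci[1, c("c", "h", "n", "o", "s", "p", "ppm_error",
                            "dbe", "oc", "hc")]
  }
  assignments <- cbind(data.frame(mz = peaks$mz, neutral_mass = neutral,
                                  status = status, n_candidates = ncand),
                       fcols)
  structure(list(assignments = assignments, candidates = cand,
                 summary = list(n_peaks = n,
                                n_unique = sum(status == "unique"),
                                n_ambiguous = sum(status == "ambiguous"),
                                n_unassigned = sum(status == "unassigned"))),
            class = "formula_assignment")
}

#' @export
print.formula_assignment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Formula assignment: %d peaks; %d unique, %d ambiguous, %d unassigned\n",
              s$n_peaks, s$n_unique, s$n_ambiguous, s$n_unassigned))
  invisible(x)
}

#' Write an assignment table as TSV
#'
#' Columns: mass_da, ppm_error, c, h, n, o, s, p, dbe, oc, hc, status.
#'
#' @param x a `formula_assignment` object.
#' @param path output file path.
#' @export
write_assignment_table <- function(x, path) {
  stopifnot(inherits(x, "formula_assignment"))
  a <- x$assignments
  tab <- data.frame(mass_da = a$neutral_mass, ppm_error = a$ppm_error,
                    c = a$c, h = a$h, n = a$n, o = a$o, s = a$s, p = a$p,
                    dbe = a$dbe, oc = a$oc, hc = a$hc, status = a$status)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
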