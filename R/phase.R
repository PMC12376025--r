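## Phase analysis: ground-truth labelling from Guinier fits, micelle
## fractions, phase maps, CMC/MCT boundary extraction, label merging and
## clustering-agreement scores.

.LABEL_OF_FORM <- c(poly_gauss_coil = "unimer", mixed = "mixed",
                    sphere = "micelle")

#' Ground-truth phase labels from Guinier forward intensities
#'
#' Emulates the expert labelling rule: the baseline `B` is the mean
#' Guinier forward intensity `i_zero` over samples whose phenol
#' concentration lies within the lowest `baseline_quantile` of the
#' phenol range; a sample is labelled `"micelle"` when
#' `i_zero > multiplier * B` (strict), else `"unimer"`.
#'
#' @param i_zero per-sample Guinier forward intensities.
#' @param phenol per-sample phenol concentrations (mg/ml).
#' @param baseline_quantile fraction of the phenol range defining the
#'   low-phenol baseline set, in (0, 1].
#' @param multiplier uptick multiplier on the baseline.
#' @return Character vector of labels (`"unimer"` / `"micelle"`).
#' @export
guinier_ground_truth <- function(i_zero, phenol, baseline_quantile = 0.2,
                                 multiplier = 1.0) {
  stopifnot(length(i_zero) == length(phenol))
  if (!is.numeric(baseline_quantile) || baseline_quantile <= 0 ||
      baseline_quantile > 1)
    config_error("baseline_quantile must be in (0, 1]")
  if (!is.numeric(multiplier) || multiplier <= 0)
    config_error("multiplier must be positive")
  cut <- min(phenol) + baseline_quantile * (max(phenol) - min(phenol))
  base <- i_zero[phenol <= cut]
  if (length(base) == 0L) config_error("empty baseline set")
  B <- mean(base)
  ifelse(i_zero > multiplier * B, "micelle", "unimer")
}

#' Micelle fraction from a mixed-model fit
#'
#' The scale of the sphere component divided by the sum of the sphere
#' and coil scales: `f = scale_b / (scale_a + scale_b)`.
#'
#' @param fit a `sas_fit` of the mixed model (or a named list/vector
#'   with `scale_a`, `scale_b`).
#' @return The micelle fraction in `[0, 1]`.
#' @export
micelle_fraction <- function(fit) {
  p <- if (inherits(fit, "sas_fit")) fit$params else unlist(fit)
  a <- p[["scale_a"]]; b <- p[["scale_b"]]
  if (a < 0 || b < 0) domain_error("micelle_fraction: scales must be >= 0")
  if (a + b == 0) domain_error("micelle_fraction undefined: both scales zero")
  unname(b / (a + b))
}

rg_effective_of <- function(fit) {
  if (is.null(fit) || !fit$converged) return(NA_real_)
  p <- fit$params
  switch(fit$form,
    poly_gauss_coil = unname(p[["rg"]]),
    guinier = unname(p[["rg"]]),
    sphere = sqrt(3 / 5) * unname(p[["radius"]]),
    mixed = {
      ## Guinier-weighted combination with forward intensities as weights
      i0_c <- p[["scale_a"]] * p[["coil_i_zero"]]
      drho <- p[["sphere_sld"]] - p[["sphere_sld_solvent"]]
      V <- 4 / 3 * pi * p[["sphere_radius"]]^3
      i0_s <- p[["scale_b"]] * V * drho^2
      rg_c2 <- p[["coil_rg"]]^2
      rg_s2 <- 3 / 5 * p[["sphere_radius"]]^2
      sqrt((i0_c * rg_c2 + i0_s * rg_s2) / (i0_c + i0_s))
    },
    NA_real_)
}

#' Build a phase map from selections and fits
#'
#' Labels each composition by the selected model's form
#' (coil -> unimer, mixed -> mixed, sphere -> micelle,
#' `NONE_OF_THE_ABOVE` -> none), attaches the Guinier-equivalent size of
#' the selected model (coil: fitted rg; sphere: `sqrt(3/5) * radius`;
#' mixed: forward-intensity-weighted combination) and, for mixed
#' selections, the micelle fraction.
#'
#' @param selections named list of `sas_selection` (one per curve).
#' @param fit_table the `sas_fit_table` the selections came from.
#' @param compositions data frame with `sample_id` and composition
#'   columns (`P188`, `phenol`, `benzyl_alcohol`), or `NULL` to use the
#'   compositions stored on the curves.
#' @return A `sas_phase_map`: data frame of phase points with attribute
#'   `"boundaries"` filled by [extract_boundaries].
#' @export
build_phase_map <- function(selections, fit_table, compositions = NULL) {
  ids <- names(selections)
  if (is.null(compositions)) {
    compositions <- do.call(rbind, lapply(ids, function(sid) {
      comp <- fit_table[[sid]][[1]]$curve$composition
      if (is.null(comp)) domain_error(sprintf("curve '%s' has no composition", sid))
      data.frame(sample_id = sid, as.list(comp))
    }))
  }
  pts <- do.call(rbind, lapply(ids, function(sid) {
    sel <- selections[[sid]]
    fits <- fit_table[[sid]]
    if (identical(sel$best, NONE_OF_THE_ABOVE)) {
      lab <- "none"; rg <- NA_real_; mf <- NA_real_; model <- NONE_OF_THE_ABOVE
    } else {
      f <- fits[[sel$best]]
      lab <- .LABEL_OF_FORM[[f$form]] %||% "none"
      rg <- rg_effective_of(f)
      mf <- if (f$form == "mixed") micelle_fraction(f) else NA_real_
      model <- sel$best
    }
    data.frame(sample_id = sid, selected_model = model, label = lab,
               rg_effective = rg, micelle_fraction = mf)
  }))
  pts <- merge(compositions, pts, by = "sample_id", sort = FALSE)
  structure(pts, class = c("sas_phase_map", "data.frame"))
}

#' Extract CMC and MCT boundary points from a phase map
#'
#' Along each composition line of fixed (P188, benzyl alcohol) ordered
#' by phenol: the CMC point is the midpoint of the first edge where the
#' label leaves `"unimer"`; the MCT point is the midpoint of the first
#' edge where the label enters `"micelle"`.  Lines without the
#' corresponding transition contribute nothing.
#'
#' @param map a `sas_phase_map` (or data frame with `P188`, `phenol`,
#'   `benzyl_alcohol`, `label`).
#' @return Data frame with columns `P188`, `benzyl_alcohol`, `boundary`
#'   (`"cmc"`/`"mct"`) and `phenol` (the edge midpoint).
#' @export
extract_boundaries <- function(map) {
  need <- c("P188", "phenol", "benzyl_alcohol", "label")
  if (!all(need %in% names(map)))
    domain_error("phase map must have P188, phenol, benzyl_alcohol, label columns")
  out <- list()
  for (key in split(seq_len(nrow(map)),
                    interaction(map$P188, map$benzyl_alcohol, drop = TRUE))) {
    line <- map[key, ]
    line <- line[order(line$phenol), ]
    if (nrow(line) < 3L)
      domain_error("phenol axis must have >= 3 levels per (P188, benzyl_alcohol) line")
    if (anyDuplicated(line$phenol))
      domain_error("duplicated phenol levels on a composition line")
    lab <- line$label
    n <- nrow(line)
    cmc_edge <- which(lab[-n] == "unimer" & lab[-1] != "unimer")[1]
    mct_edge <- which(lab[-1] == "micelle" & lab[-n] != "micelle")[1]
    mid <- function(i) (line$phenol[i] + line$phenol[i + 1]) / 2
    if (!is.na(cmc_edge))
      out[[length(out) + 1L]] <- data.frame(
        P188 = line$P188[1], benzyl_alcohol = line$benzyl_alcohol[1],
        boundary = "cmc", phenol = mid(cmc_edge))
    if (!is.na(mct_edge))
      out[[length(out) + 1L]] <- data.frame(
        P188 = line$P188[1], benzyl_alcohol = line$benzyl_alcohol[1],
        boundary = "mct", phenol = mid(mct_edge))
  }
  if (length(out) == 0L)
    return(data.frame(P188 = numeric(0), benzyl_alcohol = numeric(0),
                      boundary = character(0), phenol = numeric(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Merge phase labels
#'
#' Relabels a sequence through a complete mapping; the default merges
#' the mixed and micelle phases (the two-phase comparison against a
#' Guinier-style ground truth).
#'
#' @param labels character vector of labels.
#' @param merge_rule named character vector mapping every present label.
#' @return Relabelled character vector.
#' @export
merge_labels <- function(labels,
                         merge_rule = c(mixed = "micelle", micelle = "micelle",
                                        unimer = "unimer", none = "none")) {
  present <- unique(labels)
  unmapped <- setdiff(present, names(merge_rule))
  if (length(unmapped))
    domain_error(sprintf("merge_rule does not map label(s): %s",
                         paste(unmapped, collapse = ", ")))
  unname(merge_rule[labels])
}

#' Fowlkes-Mallows score between two labelings
#'
#' Over all unordered sample pairs, with TP the pairs co-clustered in
#' both labelings, FP co-clustered in `a` only and FN in `b` only:
#' `FMS = TP / sqrt((TP + FP) (TP + FN))`, in `[0, 1]`; defined as 0
#' when TP = 0.  A value of 1 indicates perfect agreement; the score is
#' invariant to renaming cluster labels.
#'
#' @param a,b label vectors of equal length `>= 2`.
#' @return The FMS.
#' @export
fowlkes_mallows <- function(a, b) {
  if (length(a) != length(b)) domain_error("labelings must have equal length")
  if (length(a) < 2L) domain_error("need at least 2 samples")
  ct <- table(a, b)
  choose2 <- function(x) sum(x * (x - 1) / 2)
  tp <- choose2(ct)
  tp_fp <- choose2(rowSums(ct))
  tp_fn <- choose2(colSums(ct))
  if (tp == 0) return(0)
  tp / sqrt(tp_fp * tp_fn)
}

#' Micelle-fraction summary at the phase boundaries
#'
#' Quartile summary (no distributional smoothing) of the fitted micelle
#' fraction over the mixed-region points adjacent to each boundary: the
#' first mixed point just above the CMC and the last mixed point just
#' below the MCT of each composition line.
#'
#' @param map a `sas_phase_map` with `micelle_fraction`.
#' @return Data frame with one row per boundary (`cmc`, `mct`): `q25`,
#'   `median`, `q75` and the point count `n`.
#' @export
boundary_fraction_summary <- function(map) {
  at_cmc <- c(); at_mct <- c()
  for (key in split(seq_len(nrow(map)),
                    interaction(map$P188, map$benzyl_alcohol, drop = TRUE))) {
    line <- map[key, ]
    line <- line[order(line$phenol), ]
    mx <- which(line$label == "mixed")
    if (length(mx) == 0L) next
    before_unimer <- any(line$label[seq_len(mx[1] - 1)] == "unimer")
    after_micelle <- any(line$label[-seq_len(mx[length(mx)])] == "micelle")
    if (before_unimer) at_cmc <- c(at_cmc, line$micelle_fraction[mx[1]])
    if (after_micelle) at_mct <- c(at_mct, line$micelle_fraction[mx[length(mx)]])
  }
  summarize <- function(x, nm) {
    x <- x[is.finite(x)]
    if (length(x) == 0L)
      return(data.frame(boundary = nm, q25 = NA_real_, median = NA_real_,
                        q75 = NA_real_, n = 0L))
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(boundary = nm, q25 = qs[1], median = qs[2], q75 = qs[3],
               n = length(x))
  }
  rbind(summarize(at_cmc, "cmc"), summarize(at_mct, "mct"))
}

#' @export
print.sas_phase_map <- function(x, ...) {
  cat(sprintf("<sas_phase_map: %d composition points>\n", nrow(x)))
  print(table(x$label))
  invisible(x)
}
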