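# Agonist-antagonist coactivation index of activation time series:
#   CI (%) = 100 * 2 * int min(a_ag, a_ant) / (int a_ag + int a_ant),
# integrals by the trapezoidal rule on the shared uniform time grid.

trapz <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2)
}

#' Coactivation index of two activation traces
#'
#' @param a_agonist,a_antagonist equal-length activation series in `[0, 1]`
#'   on a shared uniform time grid.
#' @return the coactivation index in percent, in `[0, 100]`; defined as 0
#'   (with a warning) when both traces integrate to zero.
#' @export
coactivation_index <- function(a_agonist, a_antagonist) {
  if (length(a_agonist) != length(a_antagonist))
    stop("activation series have mismatched lengths")
  if (any(!is.finite(a_agonist)) || any(!is.finite(a_antagonist)))
    stop("non-finite activation values")
  denom <- trapz(a_agonist) + trapz(a_antagonist)
  if (denom == 0) {
    warning("both activation traces are identically zero; CI defined as 0")
    return(0)
  }
  100 * 2 * trapz(pmin(a_agonist, a_antagonist)) / denom
}

#' Coactivation index between two muscle groups
#'
#' Computes the coactivation index for every agonist x antagonist muscle
#' combination across the two groups and returns their unweighted mean (e.g.
#' three vastus traces against two biceps femoris traces give the mean of six
#' pair indices).
#'
#' @param group_A,group_B matrices or data frames with one column per muscle
#'   (a bare vector is treated as a single muscle).
#' @return mean pairwise coactivation index, percent.
#' @export
group_pair_index <- function(group_A, group_B) {
  A <- as.matrix(group_A); B <- as.matrix(group_B)
  if (ncol(A) == 0 || ncol(B) == 0) stop("empty muscle group")
  ci <- outer(seq_len(ncol(A)), seq_len(ncol(B)),
              Vectorize(function(i, j) coactivation_index(A[, i], B[, j])))
  mean(ci)
}

#' The muscle-group pairs entering the thigh and shank indices
#' @return list of character pairs (agonist group, antagonist group).
#' @export
coactivation_pairs <- function() {
  list(thigh = list(c("vastus", "biceps_femoris"),
                    c("vastus", "semitendinosus")),
       shank = list(c("tibialis_anterior", "soleus"),
                    c("tibialis_anterior", "gastrocnemius")))
}

#' Thigh and shank coactivation report for an activation table
#'
#' Computes the four pair indices (vastus-biceps femoris,
#' vastus-semitendinosus, tibialis anterior-soleus, tibialis
#' anterior-gastrocnemius) using group averaging over all muscle
#' combinations, then the thigh index as the mean of the two thigh pairs and
#' the shank index as the mean of the two shank pairs. When the column names
#' carry `_r` / `_l` side suffixes the report is computed per side and the
#' sides averaged.
#'
#' @param activations data frame with a `time` column and one activation
#'   column per muscle.
#' @param groups named character vector mapping activation column names to
#'   group tags (from [muscle_groups()] for a model, or hand-built).
#' @return list of class `coactivation_report`: `pairs` (named vector of the
#'   four pair CIs, %), `thigh_index`, `shank_index`.
#' @export
segment_indices <- function(activations, groups) {
  cols <- setdiff(names(activations), "time")
  groups <- groups[names(groups) %in% cols]
  sides <- unique(ifelse(grepl("_r$", names(groups)), "r",
                         ifelse(grepl("_l$", names(groups)), "l", "")))
  pair_defs <- unlist(coactivation_pairs(), recursive = FALSE)
  names(pair_defs) <- c("vastus-biceps_femoris", "vastus-semitendinosus",
                        "tibialis_anterior-soleus",
                        "tibialis_anterior-gastrocnemius")
  pair_ci <- sapply(names(pair_defs), function(pn) {
    pr <- pair_defs[[pn]]
    per_side <- vapply(sides, function(s) {
      sel <- if (s == "") names(groups) else grep(paste0("_", s, "$"),
                                                  names(groups), value = TRUE)
      ga <- sel[groups[sel] == pr[1]]
      gb <- sel[groups[sel] == pr[2]]
      if (!length(ga) || !length(gb)) return(NA_real_)
      group_pair_index(activations[ga], activations[gb])
    }, numeric(1))
    per_side <- per_side[!is.na(per_side)]
    if (!length(per_side))
      stop("missing muscles for pair ", pn, ": need groups ",
           paste(pr, collapse = " and "))
    mean(per_side)
  })
  structure(list(pairs = pair_ci,
                 thigh_index = mean(pair_ci[1:2]),
                 shank_index = mean(pair_ci[3:4])),
            class = "coactivation_report")
}

#' @export
print.coactivation_report <- function(x, ...) {
  cat("Coactivation report (%)\n")
  for (nm in names(x$pairs))
    cat(sprintf("  %-34s %6.2f\n", nm, x$pairs[[nm]]))
  cat(sprintf("  thigh index %6.2f | shank index %6.2f\n",
              x$thigh_index, x$shank_index))
  invisible(x)
}

#' Gait-phase-resolved coactivation indices
#'
#' Splits the traces into gait-phase bins (relative to a cycle duration) and
#' computes the thigh/shank report per bin, the temporal analogue of the
#' trial-level index.
#'
#' @inheritParams segment_indices
#' @param cycle_duration gait cycle duration (s).
#' @param n_bins number of phase bins (default 100).
#' @return data frame with `phase`, `thigh_index`, `shank_index`.
#' @export
phase_resolved_indices <- function(activations, groups, cycle_duration,
                                   n_bins = 100) {
  phase <- (activations$time %% cycle_duration) / cycle_duration
  bin <- pmin(n_bins - 1L, floor(phase * n_bins))
  out <- lapply(sort(unique(bin)), function(b) {
    rows <- which(bin == b)
    if (length(rows) < 2) return(NULL)
    rep <- suppressWarnings(segment_indices(activations[rows, , drop = FALSE],
                                            groups))
    data.frame(phase = (b + 0.5) / n_bins, thigh_index = rep$thigh_index,
               shank_index = rep$shank_index)
  })
  do.call(rbind, out)
}
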