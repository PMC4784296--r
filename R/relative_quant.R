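## Cq-table based comparator analyses.  A Cq table is a data.frame with
## columns sample_group, target, replicate, cq and (optionally) efficiency,
## one row per reaction.  In this package Cq is the take-off point.

.check_cq <- function(cq) {
  need <- c("sample_group", "target", "replicate", "cq")
  miss <- setdiff(need, names(cq))
  if (length(miss))
    qc_stop(sprintf("Cq table lacks column(s): %s", paste(miss, collapse = ", ")),
            "bad_format")
  if (any(!is.finite(cq$cq) | cq$cq <= 0))
    qc_stop("Cq values must be positive and finite", "bad_cq")
  invisible(cq)
}

.mean_cq <- function(cq, gene, group) {
  rows <- cq$target == gene & cq$sample_group == group
  if (!any(rows)) return(NA_real_)
  mean(cq$cq[rows])
}

#' Relative expression by delta-delta-Cq
#'
#' `dCq(g) = mean Cq_target(g) - mean Cq_ref(g)`;
#' `ddCq(g) = dCq(g) - dCq(control)`; `fold(g) = 2^(-ddCq(g))`.
#' Assumes perfect doubling (E = 2) for both genes.  The control group has
#' fold 1 by construction.
#'
#' @param cq Cq table (`sample_group`, `target`, `replicate`, `cq`).
#' @param target gene of interest.
#' @param reference_target reference gene.
#' @param control_group control (calibrator) sample group.
#' @return `data.frame` with `sample_group`, `delta_cq`, `delta_delta_cq`,
#'   `fold`.
#' @export
delta_delta_cq <- function(cq, target, reference_target, control_group) {
  .check_cq(cq)
  groups <- unique(cq$sample_group)
  if (!control_group %in% groups)
    qc_stop(sprintf("control group '%s' not present", control_group), "bad_group")
  mt <- vapply(groups, .mean_cq, numeric(1), cq = cq, gene = target)
  mr <- vapply(groups, .mean_cq, numeric(1), cq = cq, gene = reference_target)
  if (anyNA(mr) || anyNA(mt))
    qc_stop(sprintf("missing %s Cq in group(s): %s",
                    if (anyNA(mr)) "reference" else "target",
                    paste(groups[is.na(mr) | is.na(mt)], collapse = ", ")),
            "missing_reference")
  dcq <- mt - mr
  ddcq <- dcq - dcq[groups == control_group]
  data.frame(sample_group = groups, delta_cq = dcq, delta_delta_cq = ddcq,
             fold = 2^(-ddcq), row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression by the Pfaffl ratio
#'
#' Uses each gene's measured amplification efficiency instead of assuming
#' perfect doubling:
#' `ratio(g) = E_target^dCq_target(g) / E_ref^dCq_ref(g)` with
#' `dCq = mean Cq(control) - mean Cq(g)` per gene.  Per-reaction
#' efficiencies are averaged arithmetically within each (group, gene).
#' Reduces exactly to [delta_delta_cq()] when all efficiencies are 2.
#'
#' @inheritParams delta_delta_cq
#' @return `data.frame` with `sample_group`, `e_target`, `e_reference`,
#'   `fold`.
#' @export
pfaffl_ratio <- function(cq, target, reference_target, control_group) {
  .check_cq(cq)
  if (is.null(cq$efficiency) || anyNA(cq$efficiency[cq$target %in%
                                                    c(target, reference_target)]))
    qc_stop(paste("per-reaction efficiencies are required for the Pfaffl ratio;",
                  "run estimate_efficiency() (or quantify_plate()) first"),
            "missing_efficiency")
  groups <- unique(cq$sample_group)
  if (!control_group %in% groups)
    qc_stop(sprintf("control group '%s' not present", control_group), "bad_group")
  mean_e <- function(gene, group)
    mean(cq$efficiency[cq$target == gene & cq$sample_group == group])
  mt_ctrl <- .mean_cq(cq, target, control_group)
  mr_ctrl <- .mean_cq(cq, reference_target, control_group)
  rows <- lapply(groups, function(g) {
    mt <- .mean_cq(cq, target, g); mr <- .mean_cq(cq, reference_target, g)
    if (is.na(mt) || is.na(mr))
      qc_stop(sprintf("missing Cq for group '%s'", g), "missing_reference")
    et <- mean_e(target, g); er <- mean_e(reference_target, g)
    data.frame(sample_group = g, e_target = et, e_reference = er,
               fold = et^(mt_ctrl - mt) / er^(mr_ctrl - mr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression from absolute quantification
#'
#' Fold change of each group's mean absolute copy number over the control
#' group, with a delta-method standard error when group SEMs are supplied.
#' No reference gene is involved.
#'
#' @param group_stats `data.frame` with `sample_group`, `mean_copies` and
#'   optionally `sem_copies` (see [aggregate_replicates()]).
#' @param control_group control sample group.
#' @return `data.frame` with `sample_group`, `fold` and (when SEMs are
#'   available) `se_fold`.
#' @export
relative_from_absolute <- function(group_stats, control_group) {
  need <- c("sample_group", "mean_copies")
  if (!all(need %in% names(group_stats)))
    qc_stop("group_stats needs columns sample_group and mean_copies", "bad_format")
  ctrl <- group_stats[group_stats$sample_group == control_group, , drop = FALSE]
  if (nrow(ctrl) != 1L)
    qc_stop(sprintf("control group '%s' not present exactly once", control_group),
            "bad_group")
  if (!is.finite(ctrl$mean_copies) || ctrl$mean_copies <= 0)
    qc_stop("control group mean copies must be positive", "bad_control_mean")
  out <- data.frame(sample_group = group_stats$sample_group,
                    fold = group_stats$mean_copies / ctrl$mean_copies,
                    stringsAsFactors = FALSE)
  if ("sem_copies" %in% names(group_stats)) {
    rel_g <- group_stats$sem_copies / group_stats$mean_copies
    rel_c <- ctrl$sem_copies / ctrl$mean_copies
    out$se_fold <- out$fold * sqrt(rel_g^2 + rel_c^2)
  }
  out
}
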