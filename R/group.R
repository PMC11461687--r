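#' Group visits into dominant pathways
#'
#' Reduces each patient visit to its ordered sequence of resource-type labels
#' and groups visits whose sequences are exactly equal. The `top_k` groups by
#' visit count are retained as the dominant pathways; their occurrence
#' proportions are renormalized over the retained set (so they sum to one and
#' can be used directly as pathway sampling weights). Position-wise sample
#' means and variances of the observed activity durations are attached as the
#' pathway's duration moments.
#'
#' @param activities activity observations from [extract_activities()].
#' @param top_k number of dominant pathway groups to retain (default 5). If
#'   larger than the number of distinct sequences, all groups are returned
#'   with a warning.
#' @return a `careflow_profiles` object, path ids `0..top_k-1` in decreasing
#'   count order. Attributes: `counts` (visit counts of the retained groups),
#'   `n_visits` (total grouped visits), `coverage` (fraction of visits
#'   captured by the retained groups).
#' @export
group_pathways <- function(activities, top_k = 5) {
  act <- data.table::as.data.table(activities)
  if (!is_count(top_k) || top_k < 1) stop_cf("top_k must be a positive integer")
  if (nrow(act) == 0) stop_cf("no activity observations to group")

  data.table::setorder(act, patient_id, ordinal)
  visits <- act[, .(seq_key = paste(resource_types, collapse = "\x1f"),
                    durs = list(duration)), by = patient_id]
  grp <- visits[, .(count = .N), by = seq_key]
  data.table::setorder(grp, -count, seq_key)
  if (top_k > nrow(grp)) {
    warning(sprintf("top_k = %d exceeds the %d distinct sequences; returning all",
                    top_k, nrow(grp)), call. = FALSE)
    top_k <- nrow(grp)
  }
  keep <- grp[seq_len(top_k)]
  total_kept <- sum(keep$count)

  seqs <- means <- vars <- vector("list", top_k)
  for (i in seq_len(top_k)) {
    key <- keep$seq_key[i]
    seqs[[i]] <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    dm <- do.call(rbind, visits[seq_key == key]$durs)
    means[[i]] <- colMeans(dm)
    vars[[i]] <- if (nrow(dm) > 1) apply(dm, 2, stats::var) else
      rep(0, ncol(dm))
  }
  out <- pathway_profiles(
    activity_sequences = seqs,
    proportions = keep$count / total_kept,
    duration_means = means,
    duration_variances = vars,
    path_ids = seq_len(top_k) - 1L
  )
  attr(out, "counts") <- keep$count
  attr(out, "n_visits") <- nrow(visits)
  attr(out, "coverage") <- total_kept / nrow(visits)
  out
}
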