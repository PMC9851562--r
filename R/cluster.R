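#' Hierarchical clustering of space-normalized trajectories
#'
#' Concatenates each trial's 100 space-normalized (x, y) points into a
#' 200-dimensional vector and clusters trials by agglomerative hierarchical
#' clustering (Euclidean distance, Ward linkage by default), cutting the tree
#' at `k` clusters. The procedure has no random component, so identical
#' inputs give identical models. Cluster mean paths are computed pointwise.
#'
#' @param snorm Output of [space_normalize()].
#' @param k Number of clusters (default 8).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D"`).
#' @param distance Distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @return A `stroop_clusters` object with `assignments` (tibble:
#'   `participant_id`, `trial_index`, `cluster`), `mean_paths` (tibble:
#'   `cluster`, `point`, `x`, `y`), `k`, `linkage`, `distance`, and
#'   `pe_clusters` (filled by [label_partial_error_clusters()], which is
#'   called with its default threshold).
#' @export
cluster_trajectories <- function(snorm, k = 8, linkage = "ward.D",
                                 distance = "euclidean") {
  wide <- snorm |>
    dplyr::arrange(.data$participant_id, .data$trial_index, .data$point) |>
    tidyr::pivot_wider(id_cols = c("participant_id", "trial_index"),
                       names_from = "point", values_from = c("x", "y"))
  n <- nrow(wide)
  if (n < k) {
    abort(paste0("Need at least k = ", k, " trajectories, got ", n))
  }
  mat <- as.matrix(dplyr::select(wide, -"participant_id", -"trial_index"))
  tree <- hclust(dist(mat, method = distance), method = linkage)
  cl <- cutree(tree, k = k)
  assignments <- tibble::tibble(
    participant_id = wide$participant_id,
    trial_index = wide$trial_index,
    cluster = as.integer(cl)
  )
  mean_paths <- snorm |>
    dplyr::inner_join(assignments, by = c("participant_id", "trial_index")) |>
    dplyr::group_by(.data$cluster, .data$point) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  model <- structure(
    list(assignments = assignments, mean_paths = mean_paths, k = k,
         linkage = linkage, distance = distance, pe_clusters = integer()),
    class = "stroop_clusters"
  )
  model$pe_clusters <- label_partial_error_clusters(model)
  model
}

#' Label partial-error clusters by their mean path
#'
#' A cluster is labelled a partial-error cluster when its mean path crosses
#' materially onto the incorrect-response side, i.e. its minimum mean
#' x-coordinate falls below `-x_threshold`. This makes the identification of
#' clusters of trajectories directed toward the incorrect response - but
#' ending at the correct one - an explicit, reproducible rule. Raising the
#' threshold can only shrink the labelled set.
#'
#' @param model A `stroop_clusters` object.
#' @param x_threshold Crossing depth in aligned x units (default 0.05).
#' @return Integer vector of partial-error cluster ids.
#' @export
label_partial_error_clusters <- function(model, x_threshold = 0.05) {
  minx <- model$mean_paths |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(min_x = min(.data$x), .groups = "drop")
  sort(minx$cluster[minx$min_x < -x_threshold])
}

#' Partial-error rates per participant and condition
#'
#' Percentage of each participant x condition cell's kept trials that fall in
#' a partial-error cluster. Empty cells are reported with `pe_rate = NA`.
#'
#' @param model A `stroop_clusters` object (with `pe_clusters` set).
#' @param trials Trial metadata covering the clustered trials (`condition`
#'   required).
#' @param pe_clusters Override of the partial-error cluster ids; defaults to
#'   the model's labelled set.
#' @return Tibble: `participant_id`, `condition`, `n_trials`, `n_pe`,
#'   `pe_rate` (percent).
#' @export
pe_rates <- function(model, trials, pe_clusters = model$pe_clusters) {
  joined <- model$assignments |>
    dplyr::inner_join(
      dplyr::select(trials, "participant_id", "trial_index", "condition"),
      by = c("participant_id", "trial_index")
    )
  grid <- tidyr::expand_grid(
    participant_id = unique(trials$participant_id),
    condition = stroop_conditions()
  )
  joined |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_pe = sum(.data$cluster %in% pe_clusters),
      .groups = "drop"
    ) |>
    dplyr::right_join(grid, by = c("participant_id", "condition")) |>
    dplyr::mutate(
      n_trials = tidyr::replace_na(.data$n_trials, 0L),
      n_pe = tidyr::replace_na(.data$n_pe, 0L),
      pe_rate = ifelse(.data$n_trials > 0, 100 * .data$n_pe / .data$n_trials,
                       NA_real_)
    ) |>
    dplyr::arrange(.data$participant_id,
                   condition_factor(.data$condition)) |>
    dplyr::mutate(condition = as.character(.data$condition))
}

#' @export
print.stroop_clusters <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat("<stroop_clusters> k = ", x$k, " (", x$linkage, ", ", x$distance,
      ")\n  sizes: ", paste(sizes, collapse = " "), "\n  partial-error clusters: ",
      if (length(x$pe_clusters)) paste(x$pe_clusters, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
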