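#' Select a diverse calibration subset by Ward clustering
#'
#' Emulates the germplasm-scanning workflow in which a few hundred
#' accessions are scanned, clustered on their normalized spectra, and a
#' diverse subset is carried forward to wet chemistry. Spectra are
#' SNV-normalized, clustered by Ward's method on squared Euclidean
#' distances, the dendrogram is cut (at a height threshold or into a
#' fixed number of clusters), and representatives are drawn per cluster
#' proportionally to cluster size — the medoid first, then the members
#' farthest from those already picked (max-min rule). The procedure is
#' fully deterministic given the input order.
#'
#' @param set A [spectra_set()].
#' @param n_target Number of samples to select (<= number of samples).
#' @param distance_threshold Dendrogram cut height on the squared
#'   Euclidean/Ward scale; default 5 (on SNV-normalized spectra).
#' @param n_clusters Alternative to `distance_threshold`: cut into
#'   exactly this many clusters.
#' @param normalize SNV-normalize spectra before distances (default TRUE).
#' @return A list with `ids` (selected sample ids), `clusters` (named
#'   integer vector of cluster labels, contiguous from 1) and `hclust`
#'   (the merge history).
#' @export
ward_select_diverse <- function(set, n_target, distance_threshold = 5,
                                n_clusters = NULL, normalize = TRUE) {
  stopifnot(inherits(set, "spectra_set"))
  n <- nrow(set$absorbance)
  if (n == 0L) stop("empty spectra set")
  if (n_target > n)
    stop("n_target (", n_target, ") exceeds number of samples (", n, ")")
  if (n_target < 1L) stop("n_target must be >= 1")
  X <- set$absorbance
  if (normalize) X <- t(apply(X, 1L, snv.default))
  d2 <- stats::dist(X)^2
  hc <- stats::hclust(d2, method = "ward.D")
  labels <- if (!is.null(n_clusters)) {
    stats::cutree(hc, k = min(n_clusters, n))
  } else {
    stats::cutree(hc, h = distance_threshold)
  }
  names(labels) <- sample_ids(set)
  k <- max(labels)
  sizes <- tabulate(labels, k)

  # proportional allocation, largest-remainder, >=1 per cluster when
  # n_target >= k; when n_target < k the largest clusters win.
  alloc <- integer(k)
  if (n_target >= k) {
    alloc[] <- 1L
    rest <- n_target - k
    if (rest > 0L) {
      quota <- sizes / n * rest
      alloc <- alloc + floor(quota)
      rem <- rest - sum(floor(quota))
      if (rem > 0L) {
        ord <- order(-(quota - floor(quota)), -sizes, seq_len(k))
        alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
      }
    }
    alloc <- pmin(alloc, sizes)
    # clusters saturated at their size free up slots for the rest
    while (sum(alloc) < n_target) {
      room <- which(alloc < sizes)
      ord <- room[order(-(sizes[room] - alloc[room]), room)]
      take <- ord[seq_len(min(length(ord), n_target - sum(alloc)))]
      alloc[take] <- alloc[take] + 1L
    }
  } else {
    ord <- order(-sizes, seq_len(k))
    alloc[ord[seq_len(n_target)]] <- 1L
  }

  Dm <- as.matrix(stats::dist(X))
  ids <- sample_ids(set)
  picked <- character(0)
  for (cl in seq_len(k)) {
    if (alloc[cl] == 0L) next
    members <- which(labels == cl)
    # medoid: member with the smallest total distance to its cluster
    sub <- Dm[members, members, drop = FALSE]
    med <- members[which.min(rowSums(sub))]
    chosen <- med
    while (length(chosen) < alloc[cl]) {
      cand <- setdiff(members, chosen)
      mind <- vapply(cand, function(i) min(Dm[i, chosen]), numeric(1))
      chosen <- c(chosen, cand[which.max(mind)])
    }
    picked <- c(picked, ids[sort(chosen)])
  }
  list(ids = picked, clusters = labels, hclust = hc)
}

#' Split reference samples into calibration and validation sets
#'
#' Samples with a value for `trait` are sorted ascending and assigned in
#' the repeating pattern C,C,V — every third rank goes to validation —
#' so both sets span the full trait range at a 2:1 ratio. For n = 121
#' this yields exactly 81 calibration and 40 validation samples. Ties in
#' the trait value are broken by sample id (stable, deterministic).
#'
#' @param refs Reference data frame (see [read_reference_table()]).
#' @param trait Trait column to sort on.
#' @return An object of class `"split_plan"`: list with
#'   `calibration_ids`, `validation_ids`, `trait`.
#' @export
rank_order_split <- function(refs, trait) {
  refs <- validate_reference_table(refs)
  if (!trait %in% names(refs)) stop("unknown trait '", trait, "'")
  keep <- !is.na(refs[[trait]])
  ids <- refs$sample_id[keep]
  vals <- refs[[trait]][keep]
  n <- length(ids)
  if (n < 3L) stop("need at least 3 samples with values for '", trait, "'")
  ord <- order(vals, ids)
  ids <- ids[ord]
  pos <- seq_len(n)
  val_idx <- pos %% 3L == 0L
  structure(list(calibration_ids = ids[!val_idx],
                 validation_ids = ids[val_idx],
                 trait = trait),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> trait '", x$trait, "': ", length(x$calibration_ids),
      " calibration / ", length(x$validation_ids), " validation\n", sep = "")
  invisible(x)
}

#' Write / read a split plan as CSV
#'
#' Two columns: `sample_id` and `set` (one of `cal`, `val`).
#' @param plan A `split_plan`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `split_plan` (read).
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  df <- data.frame(
    sample_id = c(plan$calibration_ids, plan$validation_ids),
    set = c(rep("cal", length(plan$calibration_ids)),
            rep("val", length(plan$validation_ids))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @param trait Trait name to record on the plan read back.
#' @export
read_split_plan <- function(path, trait = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "set") %in% names(df)))
    stop("split CSV needs columns sample_id, set")
  if (!all(df$set %in% c("cal", "val")))
    stop("split 'set' column must be 'cal' or 'val'")
  structure(list(calibration_ids = df$sample_id[df$set == "cal"],
                 validation_ids = df$sample_id[df$set == "val"],
                 trait = trait),
            class = "split_plan")
}

#' Pick a verification subset from ranked predictions
#'
#' After screening a large germplasm with a validated model, a small
#' subset goes back to the laboratory as a check: predictions are sorted
#' ascending and every `step`-th sample is taken, starting at the first
#' (1-based positions 1, 1+step, 1+2*step, ...). The subset size is
#' `ceiling(n / step)`; for 202 predictions at step 11 that is 19.
#'
#' @param predictions Named numeric vector (names = sample ids), or a
#'   data frame with columns `sample_id` and `predicted`.
#' @param step Positive integer stride, default 11.
#' @return Character vector of selected sample ids (ascending order of
#'   predicted value).
#' @export
select_verification_subset <- function(predictions, step = 11L) {
  if (is.data.frame(predictions)) {
    if (!all(c("sample_id", "predicted") %in% names(predictions)))
      stop("data frame needs columns sample_id, predicted")
    v <- predictions$predicted
    names(v) <- predictions$sample_id
    predictions <- v
  }
  if (length(predictions) == 0L) stop("no predictions supplied")
  if (is.null(names(predictions)) || any(!nzchar(names(predictions))))
    stop("predictions must be named by sample id")
  step <- as.integer(step)
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  ord <- order(predictions, names(predictions))
  sorted <- names(predictions)[ord]
  sorted[seq(1L, length(sorted), by = step)]
}
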