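#' Climatic preference profiles
#'
#' A `climatic_profile` is the percentage distribution of a taxon's
#' occurrences over the categories of one regionalization, together with
#' the unequivocal-assignment verdict: a taxon is unequivocally assigned
#' to the category holding strictly more than the threshold share
#' (default 75%) of its classifiable occurrences, otherwise its
#' assignment is `"equivocal"`.
#'
#' @name climatic-profiles
NULL

new_profile <- function(taxon, classification, shares, n_used,
                        n_unclassified, threshold) {
  top <- if (length(shares)) names(shares)[which.max(shares)] else NA
  assignment <- if (length(shares) && max(shares) > 100 * threshold)
    top else "equivocal"
  structure(list(taxon = taxon, classification = classification,
                 shares = shares, n_used = n_used,
                 n_unclassified = n_unclassified,
                 assignment = assignment, threshold = threshold),
            class = "climatic_profile")
}

#' @export
print.climatic_profile <- function(x, ...) {
  cat(sprintf("<climatic_profile> %s / %s (n = %d, %d unclassified): %s\n",
              x$taxon, x$classification, x$n_used, x$n_unclassified,
              x$assignment))
  print(round(x$shares, 2))
  invisible(x)
}

#' Climatic profile of one genus
#'
#' Deduplicates the genus's records to unique (longitude, latitude)
#' pairs — so a heavily resampled locality counts once — samples the
#' regionalization at each unique coordinate, and computes category
#' percentages.  Points falling in NoData cells ("unclassified") are
#' excluded from the percentage denominator but reported.
#'
#' @param records occurrence data.frame of a single genus.
#' @param layer a [regionalization()].
#' @param threshold unequivocal-assignment fraction; strictly-greater
#'   rule (a share of exactly 75% is equivocal).
#' @return a `climatic_profile`.
#' @export
genus_profile <- function(records, layer, threshold = 0.75) {
  stopifnot(nrow(records) >= 1)
  taxon <- unique(records$genus)
  if (length(taxon) != 1)
    stop("genus_profile expects records of a single genus, got: ",
         paste(taxon, collapse = ", "))
  uniq <- !duplicated(paste(records$longitude, records$latitude,
                            sep = "\r"))
  pts <- records[uniq, , drop = FALSE]
  cat_ <- sample_regionalization(pts$longitude, pts$latitude, layer)
  n_unc <- sum(cat_ == "unclassified")
  cls <- cat_[cat_ != "unclassified"]
  if (length(cls) == 0)
    stop("genus '", taxon, "' has no classifiable records")
  tab <- table(cls)
  shares <- 100 * as.numeric(tab) / length(cls)
  names(shares) <- names(tab)
  shares <- sort(shares, decreasing = TRUE)
  new_profile(taxon, layer$name, shares, n_used = length(cls),
              n_unclassified = n_unc, threshold = threshold)
}

#' Spatially regular subsample of a genus's records
#'
#' Reduces an oversampled genus to `target` records spread regularly in
#' space: a systematic rectangular grid of nodes is laid over the
#' records' bounding box (node count proportional to the box's aspect
#' ratio), each node takes its nearest not-yet-used record, the node
#' grid is densified until the yield reaches `target`, and surplus picks
#' (those farthest from their node) are dropped to land on `target`
#' exactly.  Deterministic for a given seed; with `count <= target` the
#' input is returned unchanged.
#'
#' @param records occurrence data.frame of one genus.
#' @param target subsample size (default 1000).
#' @param seed integer seed.
#' @return subset of `records` with exactly `min(nrow, target)` rows, in
#'   original record order.
#' @export
regular_subsample <- function(records, target = 1000, seed = 1) {
  n <- nrow(records)
  if (n <= target) return(records)
  x <- records$longitude; y <- records$latitude
  rngx <- range(x); rngy <- range(y)
  wx <- max(rngx[2] - rngx[1], 1e-9)
  wy <- max(rngy[2] - rngy[1], 1e-9)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  jit <- stats::runif(2)      # seeded offset of the node grid
  pick_nodes <- function(m) {
    # ~m nodes over the bounding box, aspect-ratio balanced
    nx <- max(1L, round(sqrt(m * wx / wy)))
    ny <- max(1L, ceiling(m / nx))
    gx <- rngx[1] + (seq_len(nx) - 1 + jit[1]) * wx / nx
    gy <- rngy[1] + (seq_len(ny) - 1 + jit[2]) * wy / ny
    expand.grid(x = gx, y = gy)
  }
  m <- target
  sel <- integer(0)
  for (iter in 1:20) {
    nodes <- pick_nodes(m)
    used <- rep(FALSE, n)
    sel <- integer(0)
    ndist <- numeric(0)
    for (k in seq_len(nrow(nodes))) {
      d2 <- (x - nodes$x[k])^2 + (y - nodes$y[k])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (is.finite(d2[j])) {
        used[j] <- TRUE
        sel <- c(sel, j)
        ndist <- c(ndist, d2[j])
      }
    }
    if (length(sel) >= target) break
    m <- ceiling(m * 1.3)
  }
  if (length(sel) > target) {
    keep <- order(ndist)[seq_len(target)]   # drop farthest-from-node picks
    sel <- sel[keep]
  }
  records[sort(sel), , drop = FALSE]
}

#' Clade-level climatic profile
#'
#' Pools all genera into one profile while damping taxonomic sampling
#' bias: any genus with strictly more than `oversample_cap` records is
#' first reduced to `target` records with [regular_subsample()]; the
#' remaining genera enter whole.  Percentages are computed over the
#' pooled records without cross-genus coordinate deduplication.
#'
#' @param records occurrence data.frame of all genera.
#' @param layer a [regionalization()].
#' @param oversample_cap strict threshold above which a genus is
#'   subsampled (default 1500; a genus with exactly 1500 records enters
#'   whole).
#' @param target subsample size for oversampled genera (default 1000).
#' @param seed integer seed for the subsampler.
#' @param threshold unequivocal-assignment fraction.
#' @return a `climatic_profile` with taxon `"CLADE"`.
#' @export
clade_profile <- function(records, layer, oversample_cap = 1500,
                          target = 1000, seed = 1, threshold = 0.75) {
  pieces <- lapply(split(records, records$genus), function(df) {
    if (nrow(df) > oversample_cap)
      regular_subsample(df, target = target, seed = seed)
    else df
  })
  pooled <- do.call(rbind, pieces)
  cat_ <- sample_regionalization(pooled$longitude, pooled$latitude, layer)
  n_unc <- sum(cat_ == "unclassified")
  cls <- cat_[cat_ != "unclassified"]
  if (length(cls) == 0) stop("no classifiable records in the pool")
  tab <- table(cls)
  shares <- sort(stats::setNames(100 * as.numeric(tab) / length(cls),
                                 names(tab)), decreasing = TRUE)
  new_profile("CLADE", layer$name, shares, n_used = length(cls),
              n_unclassified = n_unc, threshold = threshold)
}

#' Compare semiquantitative profiles with qualitative labels
#'
#' Scores each genus's profile against an a-priori tropical/temperate
#' label: `"agree"` when the unequivocal assignment matches the label
#' directly, `"agree-after-merge"` when it matches after applying the
#' category merge rules (e.g. subtropical unified with tropical, or warm
#' and cool temperate unified with temperate), `"equivocal"` when the
#' profile has no unequivocal assignment, else `"disagree"`.
#'
#' @param profiles list of `climatic_profile`s.
#' @param labels named character vector: genus -> label (`"tropical"` or
#'   `"temperate"`); every profiled genus must appear.
#' @param merge_rules named character vector mapping category -> merged
#'   category (e.g. `c(subtropical = "tropical")`); categories absent
#'   from the map are unchanged.
#' @return data.frame with columns `genus`, `label`, `assignment`,
#'   `agreement`.
#' @export
compare_to_qualitative <- function(profiles, labels,
                                   merge_rules = character(0)) {
  rows <- lapply(profiles, function(p) {
    if (!p$taxon %in% names(labels))
      stop("no qualitative label for genus '", p$taxon, "'")
    lab <- labels[[p$taxon]]
    a <- p$assignment
    merged <- if (a %in% names(merge_rules)) merge_rules[[a]] else a
    agreement <- if (identical(a, "equivocal")) "equivocal"
      else if (identical(a, lab)) "agree"
      else if (identical(merged, lab)) "agree-after-merge"
      else "disagree"
    data.frame(genus = p$taxon, label = lab, assignment = a,
               agreement = agreement, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write profiles as a long-format table
#'
#' One row per (taxon, classification, category): columns `taxon`,
#' `classification`, `category`, `share`, `n_used`, `n_unclassified`,
#' `assignment`.
#'
#' @param profiles list of `climatic_profile`s.
#' @param path output CSV path (`NULL` to just get the data.frame).
#' @export
profiles_to_table <- function(profiles, path = NULL) {
  rows <- lapply(profiles, function(p)
    data.frame(taxon = p$taxon, classification = p$classification,
               category = names(p$shares), share = as.numeric(p$shares),
               n_used = p$n_used, n_unclassified = p$n_unclassified,
               assignment = p$assignment, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
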