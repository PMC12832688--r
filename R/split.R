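# Stratified train/validation/test splitting with largest-remainder
# allocation, so per-class counts in every split deviate from exact
# proportionality by less than one item.

#' Split specification
#'
#' Exactly one of `ratios` / `counts` is used: `ratios` (default 80-10-10)
#' allocates split sizes by largest remainder; `counts` reproduces explicit
#' printed sizes verbatim.
#'
#' @param ratios Three nonnegative reals summing to 1.
#' @param counts Optional explicit `c(train, val, test)` sizes; overrides
#'   `ratios`.
#' @param seed Integer seed for the within-class shuffles (default 42).
#' @param stratified Preserve class proportions in every split (default
#'   `TRUE`).
#' @return A list of class `"split_spec"`.
#' @export
split_spec <- function(ratios = c(0.8, 0.1, 0.1), counts = NULL,
                       seed = 42L, stratified = TRUE) {
  if (is.null(counts)) {
    if (length(ratios) != 3 || any(ratios < 0) ||
        abs(sum(ratios) - 1) > 1e-8)
      stopf("ratios must be three nonnegative numbers summing to 1")
  } else {
    if (length(counts) != 3 || any(counts < 0) || any(counts != floor(counts)))
      stopf("counts must be three nonnegative integers")
    ratios <- NULL
  }
  structure(list(ratios = ratios, counts = counts, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Largest-remainder integer allocation of `total` across weights.
lr_alloc <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  ideal <- total * weights / sum(weights)
  base <- floor(ideal)
  short <- as.integer(total - sum(base))
  if (short > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified three-way split
#'
#' Splits indices into disjoint train/validation/test sets covering every
#' item, preserving per-class proportions to within one item per class per
#' split. Identical seeds give identical splits.
#'
#' @param labels Character or factor vector of class labels.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train`, `val`, `test`.
#' @examples
#' stratified_split(rep(c("a", "b"), c(6, 4)), split_spec(seed = 1))
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0) stopf("no labels to split")
  classes <- sort(unique(labels))
  n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(n_c == 0)) stopf("every class must have at least one item")
  totals <- if (!is.null(spec$counts)) {
    if (sum(spec$counts) != n)
      stopf("counts sum to %d but there are %d labels", sum(spec$counts), n)
    as.integer(spec$counts)
  } else lr_alloc(spec$ratios, n)

  pools <- with_seed(spec$seed, {
    lapply(classes, function(cl) {
      idx <- which(labels == cl)
      idx[sample.int(length(idx))]
    })
  })
  names(pools) <- classes

  if (!spec$stratified) {
    all_idx <- with_seed(spec$seed, sample.int(n))
    return(list(train = sort(all_idx[seq_len(totals[1])]),
                val = sort(all_idx[totals[1] + seq_len(totals[2])]),
                test = sort(all_idx[totals[1] + totals[2] +
                                      seq_len(totals[3])])))
  }

  take <- function(quota) {
    out <- integer(0)
    for (cl in classes) {
      q <- quota[[cl]]
      if (q > 0) {
        out <- c(out, pools[[cl]][seq_len(q)])
        pools[[cl]] <<- pools[[cl]][-seq_len(q)]
      }
    }
    sort(out)
  }
  # train quota from global proportions; val from the remainder, scaled to
  # the remaining pool; test takes what is left.
  q1 <- lr_alloc(n_c, totals[1]); names(q1) <- classes
  rem <- vapply(classes, function(cl) length(pools[[cl]]) - 0L, integer(1)) -
    0L
  train <- take(q1)
  rem_c <- vapply(classes, function(cl) length(pools[[cl]]), integer(1))
  q2 <- pmin(lr_alloc(n_c, totals[2]), rem_c)
  deficit <- totals[2] - sum(q2)
  while (deficit > 0) {  # borrow from classes with slack, largest first
    slack <- rem_c - q2
    j <- which.max(slack)
    q2[j] <- q2[j] + 1L
    deficit <- deficit - 1L
  }
  names(q2) <- classes
  val <- take(q2)
  test <- sort(unlist(pools, use.names = FALSE))
  list(train = train, val = val, test = test)
}

#' Export split assignments as a data frame
#'
#' @param labels The label vector that was split.
#' @param split Result of [stratified_split()].
#' @param identifiers Optional ids (defaults to the index).
#' @return Data frame (`identifier`, `label`, `split`) suitable for CSV.
#' @export
split_manifest <- function(labels, split, identifiers = seq_along(labels)) {
  assignment <- character(length(labels))
  assignment[split$train] <- "train"
  assignment[split$val] <- "val"
  assignment[split$test] <- "test"
  data.frame(identifier = identifiers, label = as.character(labels),
             split = assignment, stringsAsFactors = FALSE)
}
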