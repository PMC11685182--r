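# Stratified fold construction. The cohort is partitioned into k
# disjoint hold-out groups of size (val + test); fold i assigns group i
# to validation + test and trains on everyone else, so validation and
# test sets never overlap across folds. Stratification deals subjects
# sorted by (age_group x sex) stratum cyclically, which bounds the
# deviation of every stratum's count in every split to one subject.

#' Construct stratified cross-validation folds
#'
#' @param records list of [subject_record()]s.
#' @param k number of folds.
#' @param ratio integer triple `(train, val, test)`; must satisfy
#'   `train + val + test == length(records)` and
#'   `k * (val + test) <= length(records)`.
#' @param seed shuffling seed.
#' @return list of `k` folds, each a list
#'   `(fold_id, train_ids, val_ids, test_ids)`.
#' @export
make_folds <- function(records, k, ratio, seed = 1L) {
  n <- length(records)
  ratio <- as.integer(ratio)
  if (length(ratio) != 3L || sum(ratio) != n)
    stop_mosr("ratio (%s) must sum to the cohort size %d",
              paste(ratio, collapse = "/"), n)
  hold <- ratio[2] + ratio[3]
  if (k * hold > n)
    stop_mosr("infeasible ratio: %d folds x %d held-out > %d subjects",
              k, hold, n)
  ids <- vapply(records, `[[`, character(1), "subject_id")
  stratum <- paste(vapply(records, `[[`, character(1), "age_group"),
                   vapply(records, `[[`, character(1), "sex"), sep = "/")
  ord <- with_seed(seed, {
    # shuffle, then regroup by stratum (order within stratum stays random)
    shuffled <- sample(seq_len(n))
    unlist(split(shuffled, stratum[shuffled]), use.names = FALSE)
  })
  # deal the stratum-sorted sequence cyclically into k hold-out groups
  # (some subjects may fall into no group when k*hold < n: always train)
  group <- rep(NA_integer_, n)
  group[ord[seq_len(k * hold)]] <- rep(seq_len(k), length.out = k * hold)
  lapply(seq_len(k), function(i) {
    held <- which(group == i)
    # within the group, deal stratum-sorted members alternately into an
    # evenly interleaved val/test pattern of lengths ratio[2]/ratio[3]
    held <- held[order(match(held, ord))]
    pattern <- interleave_pattern(ratio[2], ratio[3])
    val <- held[pattern]
    test <- held[!pattern]
    list(fold_id = i,
         train_ids = ids[setdiff(seq_len(n), held)],
         val_ids = ids[val],
         test_ids = ids[test])
  })
}

# logical vector of length a+b with a TRUEs spread as evenly as possible
interleave_pattern <- function(a, b) {
  n <- a + b
  if (n == 0L) return(logical(0))
  out <- rep(FALSE, n)
  if (a > 0L) out[floor(seq_len(a) * n / a - n / (2 * a)) + 1L] <- TRUE
  stopifnot(sum(out) == a)
  out
}

#' Subset records by subject id
#' @param records list of [subject_record()]s.
#' @param ids character vector of subject ids (e.g. a fold's `train_ids`).
#' @return the matching records, in the order of `ids`.
#' @export
fold_records <- function(records, ids) {
  all_ids <- vapply(records, `[[`, character(1), "subject_id")
  records[match(ids, all_ids)]
}
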