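#' Read an evolutionary-coupling score table
#'
#' Reads a CSV table of residue-pair coupling scores, such as the ranked
#' output of a pseudolikelihood direct-coupling analysis. Two dialects are
#' supported: `intra` with columns `i,j,score` for couplings within one
#' chain, and `complex` with columns `chain_i,i,chain_j,j,score` for
#' inter-chain ("EV complex") scores. Residue indices are 1-based positions
#' in the coupling model's sequence; mapping onto structure numbering is the
#' job of [pair_distances()].
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Either `"intra"` or `"complex"`.
#' @return A `coupling_set` object: records sorted by decreasing score, ties
#'   broken by canonical pair order, duplicate canonical pairs removed
#'   (highest score kept).
#' @export
read_coupling_table <- function(path, dialect = c("intra", "complex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("coupling table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  need <- if (dialect == "intra") c("i", "j", "score") else
    c("chain_i", "i", "chain_j", "j", "score")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("coupling table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("coupling table ", path, " is empty")

  parse_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("non-numeric or non-finite ", what, " at data line ", bad[1L],
           " of ", path, " (value '", x[bad[1L]], "')")
    v
  }
  i <- parse_num(raw$i, "residue index i")
  j <- parse_num(raw$j, "residue index j")
  score <- parse_num(raw$score, "score")
  if (any(i != round(i) | j != round(j)))
    stop("residue indices must be integers in ", path)
  rec <- data.frame(
    chain_i = if (dialect == "complex") raw$chain_i else NA_character_,
    residue_i = as.integer(i),
    chain_j = if (dialect == "complex") raw$chain_j else NA_character_,
    residue_j = as.integer(j),
    score = score,
    stringsAsFactors = FALSE)
  new_coupling_set(rec, selection = NULL, source = path)
}

## Canonicalize pair order, sort by descending score (ties by canonical pair
## ascending) and drop duplicate pairs keeping the best-scoring record.
new_coupling_set <- function(records, selection = NULL, source = "") {
  same_chain <- is.na(records$chain_i) | is.na(records$chain_j) |
    records$chain_i == records$chain_j
  if (any(same_chain & records$residue_i == records$residue_j))
    stop("self-coupling (i == j on the same chain) is not a valid record")
  ci <- ifelse(is.na(records$chain_i), "", records$chain_i)
  cj <- ifelse(is.na(records$chain_j), "", records$chain_j)
  flip <- (cj < ci) | (cj == ci & records$residue_j < records$residue_i)
  if (any(flip)) {
    tmp <- records[flip, c("chain_j", "residue_j")]
    records[flip, c("chain_j", "residue_j")] <-
      records[flip, c("chain_i", "residue_i")]
    records[flip, c("chain_i", "residue_i")] <- tmp
  }
  ord <- order(-records$score,
               ifelse(is.na(records$chain_i), "", records$chain_i),
               records$residue_i,
               ifelse(is.na(records$chain_j), "", records$chain_j),
               records$residue_j)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$chain_i, records$residue_i,
               records$chain_j, records$residue_j)
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, selection = selection, source = source),
            class = "coupling_set")
}

#' @export
print.coupling_set <- function(x, ...) {
  cat("coupling_set:", nrow(x$records), "residue pairs")
  if (!is.null(x$selection))
    cat(" (selection: ", names(x$selection), " = ", x$selection[[1L]], ")",
        sep = "")
  cat("\n")
  print(utils::head(x$records, 5L))
  invisible(x)
}

#' @export
length.coupling_set <- function(x) nrow(x$records)

#' Select coupled residue pairs by rank or score cutoff
#'
#' Keeps either the `top_n` highest-scoring pairs or all pairs with
#' `score >= cutoff`. Exactly one of the two selection rules must be given.
#' Ties at a `top_n` boundary are resolved by canonical pair order so the
#' selection is reproducible.
#'
#' @param cs A `coupling_set`.
#' @param top_n Number of top-ranked pairs to keep.
#' @param cutoff Minimum score to keep.
#' @return A `coupling_set` with the subset, in the original (descending
#'   score) order.
#' @export
select_pairs <- function(cs, top_n = NULL, cutoff = NULL) {
  stopifnot(inherits(cs, "coupling_set"))
  if (is.null(top_n) == is.null(cutoff))
    stop("give exactly one of top_n or cutoff")
  rec <- cs$records
  if (!is.null(top_n)) {
    if (top_n < 1) stop("top_n must be >= 1")
    if (top_n > nrow(rec)) {
      warning("top_n = ", top_n, " exceeds the ", nrow(rec),
              " available records; returning all")
      top_n <- nrow(rec)
    }
    keep <- rec[seq_len(top_n), , drop = FALSE]
    sel <- list(top_n = top_n)
  } else {
    keep <- rec[rec$score >= cutoff, , drop = FALSE]
    if (nrow(keep) == 0L)
      stop("cutoff ", cutoff, " excludes every record")
    sel <- list(cutoff = cutoff)
  }
  new_coupling_set(keep, selection = sel, source = cs$source)
}

#' Change in the sum of coupled-pair distances (delta-SEC)
#'
#' The SEC of a conformation is the sum over selected coupled residue pairs
#' of the spatial distance between the two residues. delta-SEC is that sum
#' minus the same sum in a reference structure: positive values mean the
#' conformation is, by this measure, farther from the reference in the
#' evolutionarily coupled degrees of freedom.
#'
#' @param conf_distances Numeric vector of per-pair distances (Angstrom) in
#'   the conformation.
#' @param ref_distances Matching vector of per-pair distances in the
#'   reference structure, same pair order.
#' @param reference_id Optional identifier recorded in the result.
#' @return A `sec_score` list with elements `sec`, `delta_sec` and
#'   `reference_id`.
#' @export
delta_sec <- function(conf_distances, ref_distances, reference_id = "ref") {
  if (length(conf_distances) != length(ref_distances))
    stop("pairing error: ", length(conf_distances), " conformation vs ",
         length(ref_distances), " reference distances")
  if (any(conf_distances < 0) || any(ref_distances < 0))
    stop("distances must be non-negative")
  sec <- sum(conf_distances)
  structure(list(sec = sec,
                 delta_sec = sec - sum(ref_distances),
                 reference_id = reference_id),
            class = "sec_score")
}

#' Mean delta-SEC of a cluster of conformations
#'
#' Scores a cluster (microstate) by the average delta-SEC over a random
#' subset of its member conformations, by default 50 members; clusters with
#' fewer members than `n_samples` use all members, which makes the score the
#' exact cluster mean.
#'
#' @param member_confs List of per-pair distance vectors, one per member.
#' @param ref Reference per-pair distance vector.
#' @param n_samples Number of members to sample without replacement.
#' @param rng_seed Integer seed; the same seed always selects the same
#'   members.
#' @return Mean delta-SEC (Angstrom) over the sampled members.
#' @export
state_score <- function(member_confs, ref, n_samples = 50L, rng_seed = 1L) {
  if (length(member_confs) == 0L) stop("empty state: no member conformations")
  if (n_samples < 1) stop("n_samples must be >= 1")
  n_take <- min(n_samples, length(member_confs))
  idx <- if (n_take == length(member_confs)) {
    seq_along(member_confs)
  } else {
    with_seed(rng_seed, sample.int(length(member_confs), n_take))
  }
  mean(vapply(member_confs[idx],
              function(d) delta_sec(d, ref)$delta_sec, numeric(1L)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
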