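#' Cosine similarity between all well profiles
#'
#' @param ps A [profile_set()] (or a wells x dims matrix with row names).
#' @return Symmetric W x W matrix with unit diagonal; errors on a zero-norm
#'   profile, naming the well.
#' @export
cosine_similarity_matrix <- function(ps) {
  m <- if (inherits(ps, "profile_set")) ps$profiles else as.matrix(ps)
  nrm <- sqrt(rowSums(m^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("zero-norm profile(s): ",
         paste(rownames(m)[zero] %||% zero, collapse = ", "), call. = FALSE)
  u <- m / nrm
  s <- tcrossprod(u)
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 1
  s
}

#' Average precision of a ranked binary relevance list
#'
#' The relevance flags are in rank order (most similar first, the query
#' itself excluded). AP integrates precision over the recall steps, which
#' for binary relevance equals the mean of precision-at-rank over the
#' positions of the positives.
#'
#' @param relevant Logical vector in rank order.
#' @return AP in `[0, 1]`; errors when no positive is present (such queries
#'   must be excluded by the caller).
#' @export
average_precision <- function(relevant) {
  relevant <- as.logical(relevant)
  hits <- which(relevant)
  if (length(hits) == 0)
    stop("average precision undefined without a positive", call. = FALSE)
  mean(cumsum(relevant)[hits] / hits)
}

# Rank candidate indices for one query: descending similarity, ties broken by
# a stable secondary sort on well_id. Returns the candidate order and the
# number of candidates involved in a similarity tie.
rank_candidates <- function(sims, well_ids) {
  ord <- order(-sims, well_ids, method = "radix")
  n_ties <- sum(duplicated(sims) | duplicated(sims, fromLast = TRUE))
  list(order = ord, n_ties = n_ties)
}

new_retrieval_result <- function(task, per_query, per_compound, map,
                                 per_moa = NULL, excluded = NULL) {
  structure(list(task = task, per_query = per_query,
                 per_compound = per_compound, per_moa = per_moa,
                 map = map, excluded = excluded %||% character(0)),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> task: %s, mAP = %.4f (%d compounds", x$task,
              x$map, nrow(x$per_compound)))
  if (length(x$excluded)) cat(sprintf(", %d excluded", length(x$excluded)))
  cat(")\n")
  invisible(x)
}

#' Replicate-retrieval mean average precision
#'
#' Every treatment well queries the remaining wells ranked by cosine
#' similarity; positives are the other replicate wells of the same
#' perturbation. Query APs are averaged per compound, and the mAP is the mean
#' over compounds. With `within_plate = TRUE` each query's candidate pool is
#' restricted to its own plate.
#'
#' @param ps A [profile_set()] of treatment wells.
#' @param within_plate Restrict candidate pools per plate.
#' @return A `retrieval_result` with per-query, per-compound APs and `map`.
#' @export
replicate_retrieval_map <- function(ps, within_plate = FALSE) {
  wr <- ps$well_records
  sim <- cosine_similarity_matrix(ps)
  W <- nrow(wr)
  reps <- table(wr$perturbation_id)
  if (!any(reps >= 2))
    stop("no perturbation has two or more replicate wells", call. = FALSE)

  rows <- vector("list", W)
  for (q in seq_len(W)) {
    pool <- setdiff(seq_len(W), q)
    if (within_plate) pool <- pool[wr$plate_id[pool] == wr$plate_id[q]]
    pos <- wr$perturbation_id[pool] == wr$perturbation_id[q]
    if (!any(pos)) next
    rk <- rank_candidates(sim[q, pool], wr$well_id[pool])
    rows[[q]] <- data.frame(
      well_id = wr$well_id[q], perturbation_id = wr$perturbation_id[q],
      ap = average_precision(pos[rk$order]), n_ties = rk$n_ties,
      stringsAsFactors = FALSE)
  }
  per_query <- do.call(rbind, rows)
  if (is.null(per_query))
    stop("no query has a replicate in its candidate pool", call. = FALSE)
  per_compound <- stats::aggregate(ap ~ perturbation_id, per_query, mean)
  new_retrieval_result("replicate", per_query, per_compound,
                       map = mean(per_compound$ap))
}

# Parse "|"-separated multi-label MoA strings into a list of label vectors.
parse_moa <- function(moa) {
  lapply(strsplit(ifelse(is.na(moa), "", moa), "|", fixed = TRUE),
         function(x) x[nzchar(x)])
}

#' Mechanism-of-action retrieval mean average precision
#'
#' Queries retrieve profiles of *sister compounds*: different compounds
#' sharing at least one MoA annotation. All profiles of the query's own
#' compound are removed from its candidate pool. Compounds whose MoA has no
#' other annotated compound are excluded from the computation and reported.
#' Query APs average to compound APs; the headline mAP is the mean over
#' included compounds, and per-MoA means over compound APs are also reported.
#'
#' @param ps A [profile_set()] of treatment wells with MoA annotations in
#'   `well_records$moa` (multiple labels separated by `"|"`).
#' @return A `retrieval_result` with `per_moa` and the excluded compounds.
#' @export
moa_retrieval_map <- function(ps) {
  wr <- ps$well_records
  moa <- parse_moa(wr$moa)
  sim <- cosine_similarity_matrix(ps)
  W <- nrow(wr)

  cmpds <- unique(wr$perturbation_id)
  cmpd_moa <- lapply(cmpds, function(cp)
    unique(unlist(moa[wr$perturbation_id == cp])))
  names(cmpd_moa) <- cmpds
  has_sister <- vapply(cmpds, function(cp) {
    others <- setdiff(cmpds, cp)
    any(vapply(others, function(o)
      length(intersect(cmpd_moa[[cp]], cmpd_moa[[o]])) > 0, logical(1)))
  }, logical(1))
  excluded <- cmpds[!has_sister]
  if (!any(has_sister))
    stop("no mechanism of action is shared by two or more compounds",
         call. = FALSE)

  rows <- list()
  for (q in seq_len(W)) {
    cp <- wr$perturbation_id[q]
    if (!has_sister[[match(cp, cmpds)]]) next
    pool <- which(wr$perturbation_id != cp)
    pos <- vapply(pool, function(j)
      length(intersect(cmpd_moa[[cp]],
                       cmpd_moa[[wr$perturbation_id[j]]])) > 0, logical(1))
    rk <- rank_candidates(sim[q, pool], wr$well_id[pool])
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = wr$well_id[q], perturbation_id = cp,
      ap = average_precision(pos[rk$order]), n_ties = rk$n_ties,
      stringsAsFactors = FALSE)
  }
  per_query <- do.call(rbind, rows)
  per_compound <- stats::aggregate(ap ~ perturbation_id, per_query, mean)

  moa_rows <- list()
  for (cp in per_compound$perturbation_id) {
    for (lab in cmpd_moa[[cp]]) {
      moa_rows[[length(moa_rows) + 1L]] <- data.frame(
        moa = lab, perturbation_id = cp,
        ap = per_compound$ap[per_compound$perturbation_id == cp],
        stringsAsFactors = FALSE)
    }
  }
  per_moa <- stats::aggregate(ap ~ moa, do.call(rbind, moa_rows), mean)

  new_retrieval_result("moa", per_query, per_compound,
                       map = mean(per_compound$ap), per_moa = per_moa,
                       excluded = excluded)
}

#' Permutation null distribution for replicate-retrieval mAP
#'
#' Shuffles the perturbation labels over wells (preserving the replicate
#' multiplicities) and recomputes the replicate mAP with the similarity
#' structure fixed, yielding the null distribution of mAP when profiles carry
#' no label information.
#'
#' @param ps A [profile_set()] of treatment wells.
#' @param n_perm Number of label shuffles (>= 1000 for a stable 95% CI).
#' @param seed Integer seed.
#' @return List with `maps` (null mAP draws), `mean`, and `ci` (2.5% and
#'   97.5% quantiles).
#' @export
permutation_null_replicate_map <- function(ps, n_perm = 1000, seed = 1L) {
  wr <- ps$well_records
  sim <- cosine_similarity_matrix(ps)
  W <- nrow(wr)
  # candidate rank order per query is fixed; only the labels move
  orders <- lapply(seq_len(W), function(q) {
    pool <- setdiff(seq_len(W), q)
    pool[rank_candidates(sim[q, pool], wr$well_id[pool])$order]
  })
  labels <- wr$perturbation_id
  maps <- numeric(n_perm)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    lab <- sample(labels)
    aps <- rep(NA_real_, W)
    for (q in seq_len(W)) {
      pos <- lab[orders[[q]]] == lab[q]
      if (any(pos)) aps[q] <- average_precision(pos)
    }
    cmpd <- tapply(aps, lab, mean, na.rm = TRUE)
    maps[b] <- mean(cmpd[is.finite(cmpd)])
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(maps = maps, mean = mean(maps),
       ci = stats::quantile(maps, c(0.025, 0.975), names = FALSE))
}
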