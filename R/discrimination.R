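#' Per-marker discriminatory power between two candidate fathers
#'
#' The power of marker `k` to separate the gametes of candidates i and j,
#' given their oriented allele dosages `a` and `b` and the heterozygosity
#' weight `h`:
#' \itemize{
#'   \item `1`   if `|a - b| == 1` (homozygote vs heterozygote);
#'   \item `h`   if `|a - b| == 2` (opposing homozygotes: deterministic exclusion);
#'   \item `1/h` if `a == b == 1` (both heterozygous: weak, probabilistic signal);
#'   \item `0`   otherwise, including when either dosage is missing.
#' }
#' Vectorized over `a`/`b`.
#'
#' @param a,b dosages in `{0, 1, 2, NA}`.
#' @param h heterozygosity weight, any positive real.
#' @return numeric vector of powers.
#' @export
discriminatory_power <- function(a, b, h) {
  stopifnot(h > 0)
  d <- abs(a - b)
  p <- numeric(length(d))
  p[!is.na(d) & d == 1] <- 1
  p[!is.na(d) & d == 2] <- h
  p[!is.na(d) & d == 0 & a == 1] <- 1 / h
  p
}

pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Build the pairwise discriminatory-power tensor
#'
#' Evaluates [discriminatory_power()] for every unordered pair of candidate
#' fathers at every marker. Pairs whose total available power (over *all*
#' markers) is below `h` cannot be discriminated by any marker subset and
#' are flagged (not removed; see [drop_infeasible_pairs()]).
#'
#' @param panel a [genotype_panel].
#' @param h heterozygosity weight (the per-pair power each feasible marker
#'   set must reach).
#' @return an object of class `pair_power`: `P` (pairs x markers matrix),
#'   `pairs` (data.frame i, j, id_i, id_j), `marker_ids`, `h`, `total`
#'   (per-pair power over all markers), `infeasible` (row indices).
#' @export
build_pair_power <- function(panel, h) {
  n <- n_fathers(panel)
  if (n < 2L) stop("need at least 2 candidate fathers")
  stopifnot(h > 0)
  d <- panel$dosages
  pr <- pair_index(n)
  P <- matrix(0, nrow(pr), n_markers(panel),
              dimnames = list(NULL, panel$marker_ids))
  for (i in seq_len(n - 1L)) {
    rows <- which(pr[, "i"] == i)
    ai <- d[, i]
    for (r in rows) {
      P[r, ] <- discriminatory_power(ai, d[, pr[r, "j"]], h)
    }
  }
  total <- rowSums(P)
  infeasible <- which(total < h - 1e-9)
  if (length(infeasible))
    message(length(infeasible),
            " candidate pair(s) cannot reach h even with all markers")
  structure(
    list(P = P,
         pairs = data.frame(i = pr[, "i"], j = pr[, "j"],
                            id_i = panel$individual_ids[pr[, "i"]],
                            id_j = panel$individual_ids[pr[, "j"]]),
         marker_ids = panel$marker_ids,
         h = h, total = total, infeasible = infeasible),
    class = "pair_power")
}

#' @export
print.pair_power <- function(x, ...) {
  cat(sprintf("pair_power: %d pairs x %d markers, h = %g, %d infeasible pair(s)\n",
              nrow(x$P), ncol(x$P), x$h, length(x$infeasible)))
  invisible(x)
}

#' Build the strictly triangular adjacency weight matrix Q
#'
#' `q[k, l]` (for marker index k > l in `marker_ids` order) penalizes
#' co-selecting physically close markers: 1 for pairs on different
#' chromosomes (assumed linkage equilibrium), `(|B_k - B_l| / D)^-1` for
#' same-chromosome pairs where `D` is the chromosome's physical length, and
#' 0 for `k <= l`. Same-chromosome weights therefore grow without bound as
#' markers get closer; they are kept exact (no capping).
#'
#' Markers absent from the map are placed on their own pseudo-chromosome
#' (weight 1 against everything) with a warning: no distance penalty can be
#' claimed for them.
#'
#' @param map a [marker_map].
#' @param marker_ids ordered marker ids indexing the matrix.
#' @return an object of class `adjacency_matrix`: `q` (dense lower-triangular
#'   matrix) and `marker_ids`.
#' @export
build_adjacency <- function(map, marker_ids) {
  m <- length(marker_ids)
  lk <- map_lookup(map, marker_ids, require_all = FALSE)
  chrom <- lk$chrom
  pos <- lk$pos
  unmapped <- is.na(lk$idx)
  if (any(unmapped)) {
    warning(sum(unmapped), " unmapped marker(s) treated as isolated ",
            "(unit adjacency weight against everything): ",
            paste(utils::head(marker_ids[unmapped], 5L), collapse = ", "))
    chrom[unmapped] <- paste0(".pseudo", which(unmapped))
    pos[unmapped] <- 0
  }
  chrlen <- map$chrom_lengths
  chrlen[paste0(".pseudo", which(unmapped))] <- 1
  same <- outer(chrom, chrom, "==")
  dup <- same & outer(pos, pos, "==")
  diag(dup) <- FALSE
  if (any(dup)) {
    k <- which(dup, arr.ind = TRUE)[1L, ]
    stop("coincident same-chromosome positions (adjacency weight undefined): ",
         marker_ids[k[1L]], " and ", marker_ids[k[2L]])
  }
  q <- matrix(0, m, m, dimnames = list(marker_ids, marker_ids))
  lt <- lower.tri(q)
  dist <- abs(outer(pos, pos, "-"))
  dk <- matrix(chrlen[chrom], m, m)  # D of the row (first) index's chromosome
  q[lt] <- ifelse(same[lt], (dist[lt] / dk[lt])^-1, 1)
  structure(list(q = q, marker_ids = marker_ids), class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("adjacency_matrix: %d markers, %d same-chromosome pair(s) with q > 1\n",
              length(x$marker_ids), sum(x$q > 1)))
  invisible(x)
}

# symmetric view q[k,l] + q[l,k]; used for incremental g updates
adjacency_sym <- function(Q) Q$q + t(Q$q)

marker_idx <- function(ids, markers) {
  idx <- match(markers, ids)
  if (anyNA(idx))
    stop("marker(s) not in index: ",
         paste(utils::head(markers[is.na(idx)], 5L), collapse = ", "))
  idx
}

#' Adjacency objective g(x) of a marker set
#'
#' `g = x' Q x`: the sum of adjacency weights over all selected marker
#' pairs. 0 for empty or singleton sets; monotone non-decreasing under
#' marker addition.
#'
#' @param markers character vector of selected marker ids.
#' @param Q an [build_adjacency()] result.
#' @return non-negative scalar.
#' @export
objective_g <- function(markers, Q) {
  if (length(markers) <= 1L) return(0)
  idx <- marker_idx(Q$marker_ids, markers)
  sum(Q$q[idx, idx])
}

#' Depth of a marker set: median per-pair discriminatory power
#'
#' For each candidate pair, sums the selected markers' powers; returns the
#' median over pairs (midpoint of the two central values for even pair
#' counts). Depth measures the redundancy buffer above the feasibility
#' requirement `h` and so predicts tolerance to missing genotypes.
#'
#' @param markers selected marker ids (possibly empty).
#' @param P a [build_pair_power()] result.
#' @return non-negative scalar.
#' @export
solution_depth <- function(markers, P) {
  if (nrow(P$P) == 0L) return(0)
  if (!length(markers)) return(0)
  idx <- marker_idx(P$marker_ids, markers)
  stats::median(rowSums(P$P[, idx, drop = FALSE]))
}

#' Check feasibility of a marker set against the pair constraints
#'
#' A set is feasible iff every candidate pair's summed power over the
#' selected markers reaches the heterozygosity weight `h`.
#'
#' @param markers selected marker ids.
#' @param P a [build_pair_power()] result.
#' @param h heterozygosity weight (defaults to the tensor's own).
#' @return list with `feasible` (logical) and `violations` (data.frame of
#'   pair ids and their sums, empty when feasible).
#' @export
check_feasible <- function(markers, P, h = P$h) {
  sums <- if (length(markers)) {
    rowSums(P$P[, marker_idx(P$marker_ids, markers), drop = FALSE])
  } else rep(0, nrow(P$P))
  bad <- which(sums < h - 1e-9)
  list(feasible = length(bad) == 0L,
       violations = data.frame(P$pairs[bad, c("id_i", "id_j"), drop = FALSE],
                               sum = sums[bad], row.names = NULL))
}

#' Construct a marker solution object
#'
#' @param selected ordered marker ids.
#' @param P a [build_pair_power()] result used for depth/feasibility.
#' @param Q optional [build_adjacency()] result for g (NA if absent).
#' @param h heterozygosity weight under which feasibility is evaluated.
#' @param method label of the producing optimizer.
#' @return object of class `marker_solution` with `selected`, `f`, `g`,
#'   `depth`, `feasible`, `h_used`, `method`.
#' @export
marker_solution <- function(selected, P, Q = NULL, h = P$h, method = "manual") {
  chk <- check_feasible(selected, P, h)
  structure(
    list(selected = selected,
         f = length(selected),
         g = if (is.null(Q)) NA_real_ else objective_g(selected, Q),
         depth = solution_depth(selected, P),
         feasible = chk$feasible,
         h_used = h,
         method = method),
    class = "marker_solution")
}

#' @export
print.marker_solution <- function(x, ...) {
  cat(sprintf("marker_solution [%s]: f = %d, g = %s, depth = %.3f, %s (h = %g)\n",
              x$method, x$f,
              if (is.na(x$g)) "NA" else sprintf("%.3f", x$g),
              x$depth,
              if (x$feasible) "feasible" else "INFEASIBLE", x$h_used))
  invisible(x)
}

#' Write per-pair diagnostics for a solution
#'
#' @param solution a [marker_solution].
#' @param P a [build_pair_power()] result.
#' @param path output TSV path.
#' @export
write_pair_diagnostics <- function(solution, P, path) {
  idx <- marker_idx(P$marker_ids, solution$selected)
  sums <- if (length(idx)) rowSums(P$P[, idx, drop = FALSE]) else rep(0, nrow(P$P))
  df <- data.frame(P$pairs[, c("id_i", "id_j")],
                   total_power = P$total,
                   selected_sum = sums,
                   feasible = sums >= solution$h_used - 1e-9)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
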