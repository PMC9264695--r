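#' Greedy marker selection under the pair-power constraints
#'
#' Builds a feasible marker set by repeatedly adding the marker with the
#' greatest effect per unit of adjacency penalty. A residual matrix `r_ij`
#' starts at `h` for every candidate pair; the gain of marker k is
#' `z_k(r) = sum over pairs of min(p_ijk, r_ij)` (power already covered is
#' not re-counted), and its effect is `e_k(r) = z_k(r) / denom(k)` with
#' `denom(k) = 1 + sum over markers l of [q_kl > 1]` — a static
#' same-chromosome marker-density penalty (markers in crowded regions are
#' discounted; the `+1` keeps isolated markers well-defined and the measure
#' power-driven). After adding k, `r_ij <- r_ij - min(p_ijk, r_ij)`;
#' selection stops when `r = 0` (all pairs covered). Ties on `e_k` break to
#' the lowest marker index, so the result is deterministic.
#'
#' @param P a [build_pair_power()] result with infeasible pairs dropped.
#' @param Q optional [build_adjacency()] result; without it the denominator
#'   is 1 (pure power greedy).
#' @param h heterozygosity weight.
#' @return a feasible [marker_solution] (markers in selection order).
#' @export
greedy_select <- function(P, Q = NULL, h = P$h) {
  Pm <- P$P
  m <- ncol(Pm)
  eps <- 1e-9
  denom <- if (is.null(Q)) rep(1, m) else 1 + colSums(adjacency_sym(Q) > 1)
  r <- rep(h, nrow(Pm))
  sel <- integer(0)
  while (any(r > eps)) {
    z <- colSums(pmin(Pm, r))
    z[sel] <- -Inf
    e <- z / denom
    k <- which.max(e)  # ties: lowest index
    if (!is.finite(e[k]) || z[k] <= eps) {
      stuck <- which(r > eps)
      stop("uncoverable residual: no marker adds power for pair(s) ",
           paste(utils::head(paste(P$pairs$id_i[stuck], P$pairs$id_j[stuck],
                                   sep = "|"), 5L), collapse = ", "))
    }
    r <- r - pmin(Pm[, k], r)
    sel <- c(sel, k)
  }
  marker_solution(P$marker_ids[sel], P, Q, h, method = "greedy")
}

#' Absolute genotypic correlation between markers
#'
#' Symmetric matrix of |Pearson correlation| between marker dosage vectors
#' across the candidate fathers, pairwise complete over non-missing
#' entries; undefined correlations (zero variance, too few complete pairs)
#' are set to 0. Used to rank replacement candidates in the 2-flip
#' neighborhood search: a marker highly correlated with s is the most
#' plausible substitute for s.
#'
#' @param panel a [genotype_panel] with at least 2 markers.
#' @return m x m matrix of correlation magnitudes.
#' @export
genotype_correlation <- function(panel) {
  if (n_markers(panel) < 2L) stop("need at least 2 markers")
  cc <- suppressWarnings(
    stats::cor(t(panel$dosages), use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  abs(cc)
}

flip_candidates <- function(s, selected, correlations, m, v) {
  nonsel <- setdiff(seq_len(m), selected)
  n_cand <- max(1L, ceiling(v * length(nonsel)))
  if (is.null(correlations)) return(nonsel[seq_len(min(n_cand, length(nonsel)))])
  ranked <- nonsel[order(-correlations[nonsel, s], nonsel)]
  ranked[seq_len(min(n_cand, length(ranked)))]
}

#' One/two-flip neighborhood search around a feasible marker set
#'
#' Iteratively improves a feasible starting solution. Each round first runs
#' a 1-flip pass (drop any selected marker whose removal preserves
#' feasibility — f falls, g cannot rise), then a 2-flip pass: for each
#' selected marker s, the top `ceil(v * #non-selected)` non-selected markers
#' ranked by genotypic correlation with s (at least one) are tried as
#' replacements; a swap is accepted when it stays feasible and either
#' strictly decreases g, or ties g while increasing the depth (median
#' per-pair power) — the depth tie-break staves off early convergence.
#' First-improvement within a pass; all orders are by marker index, so the
#' search is deterministic. Stops after a round with no change or
#' `max_rounds`.
#'
#' @param start a feasible [marker_solution].
#' @param P a [build_pair_power()] result (infeasible pairs dropped).
#' @param Q an [build_adjacency()] result (required: g guides acceptance).
#' @param h heterozygosity weight.
#' @param v flip fraction in `[0, 1]`.
#' @param max_rounds maximum improvement rounds.
#' @param correlations matrix from [genotype_correlation()]; `NULL` ranks
#'   candidates by marker index only.
#' @return a [marker_solution] with `f <= start$f` and `g <= start$g`.
#' @export
neighborhood_search <- function(start, P, Q, h = P$h, v = 0.2,
                                max_rounds = 50L, correlations = NULL) {
  stopifnot(v >= 0, v <= 1)
  Pm <- P$P
  m <- ncol(Pm)
  eps <- 1e-9
  qsym <- adjacency_sym(Q)
  sel <- sort(marker_idx(P$marker_ids, start$selected))
  sums <- if (length(sel)) rowSums(Pm[, sel, drop = FALSE]) else rep(0, nrow(Pm))
  if (any(sums < h - eps)) stop("neighborhood search requires a feasible start")
  g_cur <- if (length(sel) > 1L) sum(qsym[sel, sel]) / 2 else 0

  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    # 1-flip: drop redundant markers (ascending index)
    for (s in sel) {
      trial <- sums - Pm[, s]
      if (all(trial >= h - eps)) {
        sums <- trial
        sel <- setdiff(sel, s)
        g_cur <- g_cur - (if (length(sel)) sum(qsym[s, sel]) else 0)
        changed <- TRUE
      }
    }
    # 2-flip: swap s -> t among correlation-ranked candidates
    for (s in sel) {
      rest <- setdiff(sel, s)
      cand <- flip_candidates(s, sel, correlations, m, v)
      base <- sums - Pm[, s]
      gs <- if (length(rest)) sum(qsym[s, rest]) else 0
      depth_cur <- NULL
      for (t in cand) {
        trial <- base + Pm[, t]
        if (any(trial < h - eps)) next
        dg <- (if (length(rest)) sum(qsym[t, rest]) else 0) - gs
        accept <- dg < -eps
        if (!accept && abs(dg) <= eps) {
          if (is.null(depth_cur)) depth_cur <- stats::median(sums)
          accept <- stats::median(trial) > depth_cur + eps
        }
        if (accept) {
          sel <- sort(c(rest, t))
          sums <- trial
          g_cur <- g_cur + dg
          changed <- TRUE
          break  # first improvement: move on to the next s
        }
      }
    }
    if (!changed) break
  }
  out <- marker_solution(P$marker_ids[sel], P, Q, h, method = "greedy+ns")
  stopifnot(out$feasible, out$f <= start$f)
  out
}

#' Optimize a marker set for paternity exclusion
#'
#' High-level dispatcher: builds the pair-power tensor and (when a map is
#' given) the adjacency matrix, drops undiscriminable pairs, and runs the
#' requested optimizer. `"greedy+ns"` is [neighborhood_search()] applied to
#' [greedy_select()]; `"ilp-count"` and `"ilp-quad"` are the exact
#' branch-and-bound solvers.
#'
#' @param panel a filtered [genotype_panel].
#' @param map a [marker_map]; required unless `method = "ilp-count"`.
#' @param h heterozygosity weight.
#' @param method one of `"greedy+ns"`, `"greedy"`, `"ilp-count"`, `"ilp-quad"`.
#' @param v flip fraction for the neighborhood search.
#' @param time_limit seconds, for the exact solvers.
#' @param max_rounds neighborhood-search round cap.
#' @return object of class `optimize_result`: `solution`
#'   ([marker_solution]), `report` (`solve_report`, exact methods only),
#'   `dropped_pairs` (data.frame), `h`, `method`.
#' @export
optimize_markers <- function(panel, map = NULL, h,
                             method = c("greedy+ns", "greedy", "ilp-count",
                                        "ilp-quad"),
                             v = 0.2, time_limit = 3600, max_rounds = 50L) {
  method <- match.arg(method)
  if (is.null(map) && method != "ilp-count")
    stop("a marker map is required for method '", method,
         "' (adjacency weights need positions)")
  P0 <- build_pair_power(panel, h)
  dp <- drop_infeasible_pairs(P0, h)
  P <- dp$tensor
  Q <- if (!is.null(map)) build_adjacency(map, panel$marker_ids)
  report <- NULL
  solution <- switch(
    method,
    "greedy" = greedy_select(P, Q, h),
    "greedy+ns" = {
      g0 <- greedy_select(P, Q, h)
      neighborhood_search(g0, P, Q, h, v = v, max_rounds = max_rounds,
                          correlations = genotype_correlation(panel))
    },
    "ilp-count" = {
      report <- solve_min_count(P, h, Q, time_limit = time_limit)
      report$solution
    },
    "ilp-quad" = {
      report <- solve_min_adjacency(P, Q, h, time_limit = time_limit)
      report$solution
    })
  if (!is.null(report) && report$status == "infeasible")
    stop("model infeasible after dropping pairs; certificate pairs: ",
         paste(report$certificate$id_i, report$certificate$id_j,
               sep = "|", collapse = ", "))
  structure(list(solution = solution, report = report,
                 dropped_pairs = dp$dropped, h = h, method = method,
                 pair_power = P, adjacency = Q),
            class = "optimize_result")
}

#' @export
print.optimize_result <- function(x, ...) {
  cat(sprintf("optimize_result [%s, h = %g]: %d dropped pair(s)\n",
              x$method, x$h, nrow(x$dropped_pairs)))
  print(x$solution)
  invisible(x)
}

#' Write a marker solution as TSV with a JSON metrics sidecar
#'
#' @param result an `optimize_result` (or a [marker_solution]).
#' @param map optional [marker_map] to annotate chromosome/position.
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
write_solution <- function(result, map = NULL, out_dir) {
  sol <- if (inherits(result, "marker_solution")) result else result$solution
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(marker = sol$selected)
  if (!is.null(map)) {
    lk <- map_lookup(map, sol$selected, require_all = FALSE)
    df$chrom <- lk$chrom
    df$pos <- lk$pos
  }
  tsv <- file.path(out_dir, "solution.tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(out_dir, "solution_metrics.json")
  jsonlite::write_json(
    list(f = sol$f, g = sol$g, depth = sol$depth, h = sol$h_used,
         feasible = sol$feasible, method = sol$method,
         status = if (!inherits(result, "marker_solution") &&
                      !is.null(result$report)) result$report$status
                  else sol$method),
    js, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(solution = tsv, metrics = js))
}
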