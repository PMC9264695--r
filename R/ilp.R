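#' Drop candidate pairs that no marker subset can discriminate
#'
#' A pair whose total power over all markers is below `h` (clones, or
#' duplicated accessions in real germplasm) makes the whole program
#' infeasible; removing it lets the optimizers run on the remaining pairs,
#' which the caller must report. Solutions are then feasible with respect to
#' the reduced tensor only.
#'
#' @param P a [build_pair_power()] result.
#' @param h heterozygosity weight (defaults to the tensor's own).
#' @return list with `tensor` (reduced `pair_power`) and `dropped`
#'   (data.frame of removed pairs with their total power).
#' @export
drop_infeasible_pairs <- function(P, h = P$h) {
  bad <- which(P$total < h - 1e-9)
  dropped <- data.frame(P$pairs[bad, c("id_i", "id_j"), drop = FALSE],
                        total_power = P$total[bad], row.names = NULL)
  if (!length(bad)) return(list(tensor = P, dropped = dropped))
  keep <- setdiff(seq_len(nrow(P$P)), bad)
  reduced <- structure(
    list(P = P$P[keep, , drop = FALSE],
         pairs = P$pairs[keep, , drop = FALSE],
         marker_ids = P$marker_ids,
         h = h,
         total = P$total[keep],
         infeasible = integer(0)),
    class = "pair_power")
  list(tensor = reduced, dropped = dropped)
}

#' Build the linearized model for the adjacency objective
#'
#' The quadratic objective `g(x) = x' Q x` is linearized with one binary
#' dummy variable `y_kl = x_k x_l` per marker pair with `q_kl > 0` (k > l),
#' tied to x by the standard linking rows
#' `x_k + x_l - y_kl <= 1`, `x_k - y_kl >= 0`, `x_l - y_kl >= 0`.
#' The model object records the variables, the pair-power constraint rows,
#' and the objective coefficients; it is used for reporting and for the
#' post-hoc soundness check that the returned assignment satisfies
#' `y_kl = x_k * x_l` exactly.
#'
#' @param P a [build_pair_power()] result (no infeasible pairs).
#' @param Q an [build_adjacency()] result over the same markers.
#' @param h heterozygosity weight.
#' @return object of class `linearized_model`.
#' @export
build_linearized_model <- function(P, Q, h = P$h) {
  stopifnot(identical(P$marker_ids, Q$marker_ids))
  yk <- which(Q$q > 0, arr.ind = TRUE)  # rows k > l only (strict lower triangle)
  structure(
    list(x_vars = P$marker_ids,
         y_pairs = data.frame(k = yk[, 1L], l = yk[, 2L]),
         y_coef = Q$q[yk],
         n_power_rows = nrow(P$P),
         n_linking_rows = 3L * nrow(yk),
         h = h),
    class = "linearized_model")
}

check_linearization <- function(model, x) {
  k <- model$y_pairs$k
  l <- model$y_pairs$l
  y <- x[k] * x[l]
  ok <- all(x[k] + x[l] - y <= 1) && all(x[k] - y >= 0) && all(x[l] - y >= 0)
  list(y = y, linking_ok = ok, objective = sum(model$y_coef * y))
}

new_solve_report <- function(status, objective, solution, wall_time, gap = NA_real_,
                             certificate = NULL) {
  structure(list(status = status, objective = objective, solution = solution,
                 wall_time = wall_time, backend = "snppick-bnb",
                 gap = if (status == "optimal") 0 else gap,
                 certificate = certificate),
            class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("solve_report [%s]: status = %s, objective = %s, %.2fs\n",
              x$backend, x$status,
              if (is.null(x$objective) || is.na(x$objective)) "NA"
              else format(x$objective), x$wall_time))
  invisible(x)
}

# ---- exact depth-first branch and bound over binary marker variables ----
#
# Both models share structure: pick a 0/1 vector over markers subject to the
# pair-power covering rows sum_k p_ijk x_k >= h. solve_min_count minimizes the
# cardinality; solve_min_adjacency minimizes g(x) = x'Qx, whose value only
# grows as markers are added (all q > 0 for k > l), so the partial objective
# is itself an admissible bound. Markers are branched in descending order of
# initial greedy effect so good incumbents are found early; suffix maxima and
# sums of the power matrix give infeasibility pruning and (for cardinality) a
# covering lower bound.
bnb_solve <- function(Pm, h, objective = c("count", "adjacency"), qsym = NULL,
                     time_limit = 3600, incumbent = NULL, g_cap = Inf) {
  objective <- match.arg(objective)
  m <- ncol(Pm)
  npairs <- nrow(Pm)
  eps <- 1e-9
  t0 <- proc.time()[["elapsed"]]

  if (npairs == 0L)
    return(list(selected = integer(0), optimal = TRUE, nodes = 1L))

  # static branching order: repeated greedy effect on the full residual
  z0 <- colSums(pmin(Pm, h))
  ord <- order(-z0, seq_len(m))
  Po <- Pm[, ord, drop = FALSE]
  qo <- if (!is.null(qsym)) qsym[ord, ord, drop = FALSE]

  # suffix structures over the branching order: suffmax[, k] / suffsum[, k]
  # describe markers k..m still available at depth k
  suffmax <- matrix(0, npairs, m + 1L)
  suffsum <- matrix(0, npairs, m + 1L)
  for (k in m:1) {
    suffmax[, k] <- pmax(suffmax[, k + 1L], Po[, k])
    suffsum[, k] <- suffsum[, k + 1L] + Po[, k]
  }

  st <- new.env(parent = emptyenv())
  st$best_sel <- NULL
  st$best_obj <- Inf
  st$nodes <- 0L
  st$timed_out <- FALSE
  if (!is.null(incumbent) && length(incumbent)) {
    st$best_sel <- match(incumbent, ord)
    st$best_obj <- if (objective == "count") length(incumbent)
                   else sum(qsym[incumbent, incumbent]) / 2
  }

  count_lb <- function(r, k) {
    need <- r > eps
    if (!any(need)) return(0L)
    mx <- suffmax[need, k]
    if (any(mx <= eps)) return(Inf)
    max(ceiling((r[need] - eps) / mx))
  }

  recurse <- function(k, sel, r, obj) {
    st$nodes <- st$nodes + 1L
    if (st$nodes %% 2048L == 0L &&
        proc.time()[["elapsed"]] - t0 > time_limit) {
      st$timed_out <- TRUE
    }
    if (st$timed_out) return(invisible())
    if (all(r <= eps)) {
      if (obj < st$best_obj - eps) {
        st$best_obj <- obj
        st$best_sel <- sel
      }
      return(invisible())
    }
    if (k > m) return(invisible())
    # infeasibility prune: remaining markers cannot cover some residual
    if (any(r - suffsum[, k] > eps)) return(invisible())
    # bound prune
    if (objective == "count") {
      lb <- obj + count_lb(r, k)
      if (lb >= st$best_obj) return(invisible())
    } else {
      if (obj >= st$best_obj - eps) return(invisible())
    }
    # include branch
    obj_in <- if (objective == "count") obj + 1
              else obj + (if (length(sel)) sum(qo[k, sel]) else 0)
    ok_in <- if (objective == "count") obj_in < st$best_obj
             else obj_in < st$best_obj - eps && obj_in <= g_cap + eps
    if (ok_in)
      recurse(k + 1L, c(sel, k), pmax(r - Po[, k], 0), obj_in)
    # exclude branch
    recurse(k + 1L, sel, r, obj)
  }

  recurse(1L, integer(0), rep(h, npairs), 0)
  sel <- sort(ord[st$best_sel])
  list(selected = sel, optimal = !st$timed_out && is.finite(st$best_obj),
       found = is.finite(st$best_obj), nodes = st$nodes,
       timed_out = st$timed_out)
}

infeasibility_certificate <- function(P, h) {
  bad <- which(P$total < h - 1e-9)
  if (!length(bad)) bad <- order(P$total)[seq_len(min(3L, nrow(P$P)))]
  data.frame(P$pairs[bad, c("id_i", "id_j"), drop = FALSE],
             total_power = P$total[bad], row.names = NULL)
}

#' Exact minimum-cardinality marker set (branch and bound)
#'
#' Minimizes the number of selected markers subject to every candidate
#' pair's summed discriminatory power reaching `h`. Solved exactly by the
#' package's depth-first branch-and-bound; intended for moderate marker
#' counts (the covering structure prunes well, but worst case is
#' exponential — use the greedy/neighborhood heuristics at genome scale).
#'
#' @param P a [build_pair_power()] result; infeasible pairs must have been
#'   dropped first (see [drop_infeasible_pairs()]).
#' @param h heterozygosity weight.
#' @param Q optional [build_adjacency()] result, used only to report g.
#' @param time_limit seconds; on expiry the best incumbent is returned with
#'   status `feasible-not-proven`.
#' @return a `solve_report`; its `solution` is a [marker_solution].
#' @export
solve_min_count <- function(P, h = P$h, Q = NULL, time_limit = 3600) {
  t0 <- proc.time()[["elapsed"]]
  if (any(P$total < h - 1e-9)) {
    return(new_solve_report("infeasible", NA_real_, NULL,
                            proc.time()[["elapsed"]] - t0,
                            certificate = infeasibility_certificate(P, h)))
  }
  inc <- greedy_select(P, Q = NULL, h = h)$selected
  res <- bnb_solve(P$P, h, "count", time_limit = time_limit,
                   incumbent = match(inc, P$marker_ids))
  sol <- marker_solution(P$marker_ids[res$selected], P, Q, h,
                         method = "ilp-count")
  status <- if (res$optimal) "optimal" else if (res$found) "feasible-not-proven" else "timeout"
  new_solve_report(status, sol$f, sol, proc.time()[["elapsed"]] - t0)
}

#' Exact minimum-adjacency marker set (branch and bound)
#'
#' Minimizes the adjacency objective `g(x) = x' Q x` subject to the pair
#' constraints, i.e. finds the feasible marker set closest to linkage
#' equilibrium, via the linearized model (`y_kl = x_k x_l`). No cardinality
#' term is added; optionally a secondary lexicographic pass fixes the
#' optimal `g*` and minimizes the marker count among sets attaining it.
#' The reported objective is recomputed independently through
#' [objective_g()] and must agree with the model objective within 1e-6.
#'
#' @param P a [build_pair_power()] result (infeasible pairs dropped).
#' @param Q an [build_adjacency()] result over the same markers.
#' @param h heterozygosity weight.
#' @param time_limit seconds.
#' @param lexicographic also minimize f among g-optimal sets (default off).
#' @return a `solve_report`; its `solution` is a [marker_solution].
#' @export
solve_min_adjacency <- function(P, Q, h = P$h, time_limit = 3600,
                                lexicographic = FALSE) {
  stopifnot(identical(P$marker_ids, Q$marker_ids))
  t0 <- proc.time()[["elapsed"]]
  if (any(P$total < h - 1e-9)) {
    return(new_solve_report("infeasible", NA_real_, NULL,
                            proc.time()[["elapsed"]] - t0,
                            certificate = infeasibility_certificate(P, h)))
  }
  model <- build_linearized_model(P, Q, h)
  qsym <- adjacency_sym(Q)
  inc <- tryCatch({
    g0 <- greedy_select(P, Q, h)
    neighborhood_search(g0, P, Q, h, v = 1, correlations = NULL)$selected
  }, error = function(e) NULL)
  res <- bnb_solve(P$P, h, "adjacency", qsym = qsym, time_limit = time_limit,
                   incumbent = if (is.null(inc)) NULL else match(inc, P$marker_ids))
  selected <- P$marker_ids[res$selected]

  if (lexicographic && res$optimal && length(selected)) {
    g_star <- objective_g(selected, Q)
    res2 <- bnb_lex_min_count(P$P, h, qsym, g_star, time_limit)
    if (res2$optimal) selected <- P$marker_ids[res2$selected]
  }

  sol <- marker_solution(selected, P, Q, h, method = "ilp-quad")
  # linearization soundness: derive y from x and re-evaluate the objective
  x <- as.numeric(P$marker_ids %in% selected)
  lin <- check_linearization(model, x)
  stopifnot(lin$linking_ok)
  if (abs(lin$objective - sol$g) > 1e-6)
    stop("linearized objective disagrees with direct x'Qx evaluation")
  status <- if (res$optimal) "optimal" else if (res$found) "feasible-not-proven" else "timeout"
  rep <- new_solve_report(status, sol$g, sol, proc.time()[["elapsed"]] - t0)
  rep$model <- model
  rep
}

# lexicographic second stage: minimum cardinality among sets with g <= g_star
bnb_lex_min_count <- function(Pm, h, qsym, g_star, time_limit) {
  m <- ncol(Pm)
  eps <- 1e-9
  best <- new.env(parent = emptyenv())
  best$sel <- NULL
  best$f <- Inf
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE
  suffsum <- cbind(t(apply(Pm[, m:1, drop = FALSE], 1L, cumsum))[, m:1, drop = FALSE], 0)
  recurse <- function(k, sel, r, g) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) { timed_out <<- TRUE; return() }
    if (all(r <= eps)) {
      if (length(sel) < best$f) { best$f <- length(sel); best$sel <- sel }
      return()
    }
    if (k > m) return()
    if (length(sel) + 1L >= best$f) return()
    if (any(r - suffsum[, k] > eps)) return()
    g_in <- g + (if (length(sel)) sum(qsym[k, sel]) else 0)
    if (g_in <= g_star + 1e-6)
      recurse(k + 1L, c(sel, k), pmax(r - Pm[, k], 0), g_in)
    recurse(k + 1L, sel, r, g)
  }
  recurse(1L, integer(0), rep(h, nrow(Pm)), 0)
  list(selected = best$sel, optimal = !timed_out && is.finite(best$f))
}
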