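# fixtures and independent oracles shared across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# run the installed CLI in a child process that sees this session's library
run_cli <- function(...) {
  cli <- system.file("cli", "snppick", package = "snppick")
  suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(cli, ...),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
}

# panel straight from a dosage matrix (already oriented: mother = 0)
make_panel <- function(dosages, maternal_id = "MOM") {
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("M%02d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("I%02d", seq_len(ncol(dosages)))
  genotype_panel(dosages, maternal_id)
}

# hand-laid map over two chromosomes for toy adjacency checks
toy_map <- function(marker_ids, chrom, pos, chrom_lengths) {
  marker_map(data.frame(marker = marker_ids, chrom = chrom, pos = pos),
             chrom_lengths)
}

# small random study instance: synthetic panel + tensors, infeasible pairs
# dropped; NULL when dropping leaves no pair (caller retries another seed)
random_instance <- function(seed, n, m, h, n_chrom = 4L) {
  spec <- synthetic_panel_spec(n, m, n_chrom = n_chrom, seed = seed)
  gp <- generate_panel(spec)
  P0 <- suppressMessages(build_pair_power(gp$panel, h))
  dp <- drop_infeasible_pairs(P0, h)
  if (nrow(dp$tensor$P) == 0L) return(NULL)
  list(panel = gp$panel, map = gp$map, P = dp$tensor,
       Q = build_adjacency(gp$map, gp$panel$marker_ids), h = h)
}

# independent oracle: exhaustive enumeration over all 2^m marker subsets
brute_force_optimum <- function(Pm, h, Qq = NULL) {
  m <- ncol(Pm)
  X <- as.matrix(expand.grid(rep(list(0:1), m)))
  sums <- X %*% t(Pm)
  feas <- rowSums(sums < h - 1e-9) == 0L
  stopifnot(any(feas))
  out <- list(min_f = min(rowSums(X)[feas]))
  if (!is.null(Qq)) {
    g <- rowSums((X %*% Qq) * X)
    out$min_g <- min(g[feas])
  }
  out
}

# four-branch reference formula for the per-marker power, written directly
# from its case definition (independent of the vectorized implementation)
power_reference <- function(a, b, h) {
  if (is.na(a) || is.na(b)) return(0)
  if (abs(a - b) == 1) return(1)
  if (abs(a - b) == 2) return(h)
  if (a == 1 && b == 1) return(1 / h)
  0
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}
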