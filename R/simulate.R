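#' Specification for a synthetic candidate-parent panel
#'
#' Describes the study conditions the generator emulates: a closed
#' population of genotyped candidate fathers containing unrelated founders
#' plus close-family blocks (full-sib families, parent-offspring chains) —
#' the structures that make exclusion-based parentage hard — genotyped at
#' biallelic SNPs in linkage equilibrium.
#'
#' @param n_founders number of unrelated founder candidates.
#' @param n_markers number of biallelic markers.
#' @param maf_range minor-allele-frequency sampling interval within
#'   `[0.05, 0.5]` (uniform draw per marker); the frequency refers to the
#'   non-maternal allele.
#' @param family_blocks list of `list(type = "full-sib"|"chain", size = k)`;
#'   full-sib blocks add k offspring of two founders, chains add a k-deep
#'   parent-offspring line (each member a child of the previous member and
#'   a founder). All family members are candidate fathers too.
#' @param n_chrom number of chromosomes (default 17, a typical diploid
#'   fruit-tree karyotype).
#' @param chrom_length physical chromosome length in bp (single value or
#'   one per chromosome).
#' @param maternal_id id given to the generated mother (homozygous for the
#'   reference allele at every marker, by construction).
#' @param seed integer RNG seed; the panel is bit-identical under a fixed
#'   seed.
#' @return object of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_founders, n_markers,
                                 maf_range = c(0.05, 0.5),
                                 family_blocks = list(),
                                 n_chrom = 17L, chrom_length = 4e7,
                                 maternal_id = "MOTHER", seed = 1L) {
  stopifnot(n_founders >= 2L || length(family_blocks) > 0L, n_markers >= 1L)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0 || maf_range[2] > 0.5)
    stop("maf_range must be an interval within [0, 0.5]")
  for (b in family_blocks)
    stopifnot(b$type %in% c("full-sib", "chain"), b$size >= 1L)
  chrom_length <- rep_len(chrom_length, n_chrom)
  structure(list(n_founders = n_founders, n_markers = n_markers,
                 maf_range = maf_range, family_blocks = family_blocks,
                 n_chrom = n_chrom, chrom_length = chrom_length,
                 maternal_id = maternal_id, seed = seed),
            class = "synthetic_panel_spec")
}

# one gamete per marker from a diploid dosage vector: 0 -> 0, 2 -> 1,
# 1 -> Bernoulli(1/2), missing -> missing
draw_gamete <- function(dosage) {
  g <- integer(length(dosage))
  g[dosage == 2L] <- 1L
  het <- which(dosage == 1L)
  g[het] <- stats::rbinom(length(het), 1L, 0.5)
  g[is.na(dosage)] <- NA_integer_
  g
}

mendelian_child <- function(p1, p2) draw_gamete(p1) + draw_gamete(p2)

#' Generate a synthetic candidate-father panel and marker map
#'
#' Founder dosages are drawn from Hardy-Weinberg proportions at each
#' marker's sampled allele frequency; family-block members are produced by
#' Mendelian transmission (one gamete per marker, markers independent —
#' linkage equilibrium). Marker positions are distinct, strictly increasing
#' within chromosomes. The mother is homozygous for the reference allele at
#' every marker, so the panel is already in oriented coding.
#'
#' @param spec a [synthetic_panel_spec].
#' @return list with `panel` (a [genotype_panel]) and `map` (a
#'   [marker_map]).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  set.seed(spec$seed)
  m <- spec$n_markers
  nf <- spec$n_founders

  chrom_of <- rep_len(seq_len(spec$n_chrom), m)
  pos <- integer(m)
  for (c in seq_len(spec$n_chrom)) {
    idx <- which(chrom_of == c)
    pos[idx] <- sort(sample.int(spec$chrom_length[c] - 1L, length(idx)))
  }
  marker_ids <- sprintf("M%04d", seq_len(m))
  map <- marker_map(
    data.frame(marker = marker_ids, chrom = paste0("chr", chrom_of),
               pos = pos),
    stats::setNames(spec$chrom_length, paste0("chr", seq_len(spec$n_chrom))))

  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  founders <- matrix(stats::rbinom(m * nf, 2L, maf), nrow = m,
                     dimnames = list(marker_ids,
                                     sprintf("F%03d", seq_len(nf))))
  geno <- founders
  for (b in seq_along(spec$family_blocks)) {
    blk <- spec$family_blocks[[b]]
    if (blk$type == "full-sib") {
      par <- sample(nf, 2L)
      kids <- vapply(seq_len(blk$size), function(i)
        mendelian_child(founders[, par[1L]], founders[, par[2L]]),
        integer(m))
      colnames(kids) <- sprintf("FS%d_%02d", b, seq_len(blk$size))
      geno <- cbind(geno, kids)
    } else {  # chain: each member is a child of the previous and a founder
      cur <- founders[, sample(nf, 1L)]
      kids <- matrix(NA_integer_, m, blk$size,
                     dimnames = list(marker_ids,
                                     sprintf("PO%d_%02d", b, seq_len(blk$size))))
      for (i in seq_len(blk$size)) {
        cur <- mendelian_child(cur, founders[, sample(nf, 1L)])
        kids[, i] <- cur
      }
      geno <- cbind(geno, kids)
    }
  }
  list(panel = genotype_panel(geno, spec$maternal_id,
                              stats::setNames(rep(0L, m), marker_ids)),
       map = map)
}

#' Simulate half-sib offspring by Mendelian transmission
#'
#' The mother is homozygous for the reference allele, so each offspring
#' dosage equals the paternal gamete: 0 if the father is dosage 0, 1 if
#' dosage 2, Bernoulli(1/2) if heterozygous, missing if the paternal
#' genotype is missing. Gametes are independent across markers (linkage
#' equilibrium) and across offspring.
#'
#' @param fathers a [genotype_panel], or a dosage matrix (markers x
#'   fathers), or a single father's dosage vector.
#' @param n_offspring offspring per father (default 5, the evaluation
#'   harness's per-cross family size).
#' @param seed integer RNG seed.
#' @return object of class `offspring_set`: `dosages` (markers x
#'   offspring, values 0/1/NA), `offspring_ids`, `true_father`,
#'   `marker_ids`, `mask_rate` (0).
#' @export
simulate_offspring <- function(fathers, n_offspring = 5L, seed = 1L) {
  if (inherits(fathers, "genotype_panel")) fathers <- fathers$dosages
  if (is.null(dim(fathers)))
    fathers <- matrix(fathers, ncol = 1L,
                      dimnames = list(names(fathers), "father"))
  set.seed(seed)
  m <- nrow(fathers)
  ids <- colnames(fathers)
  out <- matrix(NA_integer_, m, ncol(fathers) * n_offspring,
                dimnames = list(rownames(fathers), NULL))
  true_father <- character(ncol(out))
  for (f in seq_len(ncol(fathers))) {
    cols <- (f - 1L) * n_offspring + seq_len(n_offspring)
    out[, cols] <- vapply(seq_len(n_offspring),
                          function(i) draw_gamete(fathers[, f]), integer(m))
    true_father[cols] <- ids[f]
  }
  off_ids <- paste0(true_father, "_o",
                    rep(seq_len(n_offspring), times = ncol(fathers)))
  colnames(out) <- off_ids
  structure(list(dosages = out, offspring_ids = off_ids,
                 true_father = stats::setNames(true_father, off_ids),
                 marker_ids = rownames(fathers), mask_rate = 0),
            class = "offspring_set")
}

#' @export
print.offspring_set <- function(x, ...) {
  cat(sprintf("offspring_set: %d offspring x %d markers (mask rate %.3g, %.2f%% missing)\n",
              length(x$offspring_ids), length(x$marker_ids), x$mask_rate,
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Randomly mask offspring genotypes
#'
#' Each (offspring, marker) cell is independently set missing with
#' probability `rate`, emulating failed genotype calls. The realized
#' missing fraction is recorded on the returned set.
#'
#' @param offspring an [offspring_set].
#' @param rate masking probability; rates above 0.2 are outside the
#'   emulated regime and warn.
#' @param seed integer RNG seed.
#' @return the masked [offspring_set].
#' @export
mask_genotypes <- function(offspring, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate > 0.2)
    warning("masking rate ", rate, " above the emulated range [0, 0.2]")
  if (rate == 0) return(offspring)
  set.seed(seed)
  d <- offspring$dosages
  d[stats::runif(length(d)) < rate] <- NA_integer_
  offspring$dosages <- d
  offspring$mask_rate <- rate
  offspring$realized_missing <- mean(is.na(d))
  offspring
}

#' Write offspring dosages and truth table as TSVs
#'
#' @param offspring an [offspring_set].
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
write_offspring <- function(offspring, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- file.path(out_dir, "offspring_dosages.tsv")
  utils::write.table(
    data.frame(marker = offspring$marker_ids, offspring$dosages,
               check.names = FALSE),
    geno, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  truth <- file.path(out_dir, "offspring_truth.tsv")
  utils::write.table(
    data.frame(offspring = offspring$offspring_ids,
               true_father = unname(offspring$true_father)),
    truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosages = geno, truth = truth))
}
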