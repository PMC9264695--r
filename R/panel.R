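#' Construct a genotype panel of candidate fathers
#'
#' A `genotype_panel` is the single source of genotype truth for marker
#' selection: an allele-dosage matrix for the candidate paternal parents,
#' oriented so that every dosage counts the allele *not* carried by the
#' (homozygous) maternal parent. The mother therefore has dosage 0 at every
#' retained marker and a paternal gamete equals the offspring dosage.
#'
#' @param dosages integer matrix, rows = markers, columns = individuals,
#'   values in `{0, 1, 2, NA}`. Row names are marker ids, column names are
#'   individual ids.
#' @param maternal_id identifier of the maternal parent (not a column).
#' @param maternal_dosages optional named vector of the mother's dosages in
#'   the *original* file coding (each 0 or 2); kept for provenance only.
#' @return an object of class `genotype_panel` with fields `dosages`,
#'   `marker_ids`, `individual_ids`, `maternal_id`, `maternal_dosages`.
#' @export
genotype_panel <- function(dosages, maternal_id, maternal_dosages = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix must carry marker ids (rownames) and individual ids (colnames)")
  bad <- !(dosages %in% c(0L, 1L, 2L)) & !is.na(dosages)
  if (any(bad))
    stop("dosage values outside {0, 1, 2, missing}: found ",
         paste(utils::head(unique(dosages[bad]), 5L), collapse = ", "))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated marker ids in panel")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicated individual ids in panel")
  if (ncol(dosages) < 2L)
    stop("need at least 2 candidate fathers (one pair to discriminate), got ",
         ncol(dosages))
  storage.mode(dosages) <- "integer"
  structure(
    list(dosages = dosages,
         marker_ids = rownames(dosages),
         individual_ids = colnames(dosages),
         maternal_id = maternal_id,
         maternal_dosages = maternal_dosages),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_panel: %d candidate fathers x %d markers (mother: %s, %.2f%% missing)\n",
              length(x$individual_ids), length(x$marker_ids),
              x$maternal_id, 100 * miss))
  invisible(x)
}

n_fathers <- function(panel) length(panel$individual_ids)
n_markers <- function(panel) length(panel$marker_ids)

subset_markers <- function(panel, keep) {
  genotype_panel(panel$dosages[keep, , drop = FALSE], panel$maternal_id,
                 panel$maternal_dosages[keep])
}

#' Load a candidate-father genotype panel
#'
#' Reads genotypes from a VCF or a dosage TSV, identifies the maternal
#' sample, drops markers at which the mother is heterozygous or missing
#' (the mother must be homozygous for the formulation to apply), and
#' re-orients all dosages as counts of the non-maternal allele so that the
#' mother carries dosage 0 everywhere. The mother is removed from the
#' candidate set unless `mother_is_candidate` (selfing scenarios).
#'
#' @param path path to the genotype file.
#' @param format `"dosage-tsv"` (rows = markers, first column the marker id,
#'   header of individual ids, cells 0/1/2 with `NA` or `.` for missing) or
#'   `"vcf"` (v4.x; only biallelic SNP records with GT are used, phasing is
#'   ignored, half-calls become missing).
#' @param maternal_id sample id of the maternal parent; must be present.
#' @param mother_is_candidate keep the mother as a candidate father.
#' @return a [genotype_panel].
#' @export
load_panel <- function(path, format = c("dosage-tsv", "vcf"), maternal_id,
                       mother_is_candidate = FALSE) {
  format <- match.arg(format)
  raw <- switch(format,
                "dosage-tsv" = read_dosage_tsv(path),
                "vcf" = read_vcf_dosages(path))
  if (!maternal_id %in% colnames(raw))
    stop("maternal id '", maternal_id, "' not among samples: ",
         paste(colnames(raw), collapse = ", "))
  mom <- raw[, maternal_id]
  keep <- !is.na(mom) & mom != 1L
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " marker(s) removed: mother heterozygous or missing")
  if (!any(keep)) stop("no informative loci: mother heterozygous or missing everywhere")
  raw <- raw[keep, , drop = FALSE]
  mom <- mom[keep]
  # orient: count the allele the mother does NOT carry
  flip <- mom == 2L
  raw[flip, ] <- 2L - raw[flip, , drop = FALSE]
  if (!mother_is_candidate)
    raw <- raw[, setdiff(colnames(raw), maternal_id), drop = FALSE]
  genotype_panel(raw, maternal_id, maternal_dosages = stats::setNames(mom, rownames(raw)))
}

read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", "."))
  if (ncol(df) < 2L) stop("dosage TSV needs a marker-id column plus samples")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(m))
  if (any(!is.na(m) & (is.na(num) | !num %in% c(0, 1, 2))))
    stop("dosage values outside {0, 1, 2, missing} in ", path)
  out <- matrix(as.integer(num), nrow = nrow(m),
                dimnames = list(ids, colnames(m)))
  out
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (sum(!snp) > 0L)
    message(sum(!snp), " multiallelic/non-SNP record(s) dropped")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  ids <- fix[snp, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"])[noid]
  dos <- gt_to_dosage(gt)
  rownames(dos) <- ids
  dos
}

gt_to_dosage <- function(gt) {
  # unphased or phased diploid GT; any half-call or '.' allele -> missing
  clean <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- matrix(map[clean], nrow = nrow(gt), dimnames = dimnames(gt))
  out
}

#' Write a panel as a dosage TSV
#'
#' The mother is written back as a column of zeros (the oriented coding), so
#' the file round-trips through [load_panel()] exactly. Missing dosages are
#' written as `NA`.
#'
#' @param panel a [genotype_panel].
#' @param path output path.
#' @export
write_dosage_tsv <- function(panel, path) {
  m <- panel$dosages
  full <- cbind(m, matrix(0L, nrow(m), 1L,
                          dimnames = list(NULL, panel$maternal_id)))
  df <- data.frame(marker = rownames(m), full, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a marker map
#'
#' @param map data.frame with columns `marker`, `chrom`, `pos` (base pairs,
#'   non-negative integers).
#' @param chrom_lengths named numeric vector of per-chromosome physical
#'   lengths in base pairs.
#' @return an object of class `marker_map`.
#' @export
marker_map <- function(map, chrom_lengths) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in map")
  if (any(map$pos < 0)) stop("negative positions in map")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  unknown <- setdiff(map$chrom, names(chrom_lengths))
  if (length(unknown))
    stop("chromosomes without a length: ", paste(unknown, collapse = ", "))
  over <- map$pos > chrom_lengths[map$chrom]
  if (any(over))
    stop("marker position beyond chromosome length: ",
         paste(map$marker[over][seq_len(min(5L, sum(over)))], collapse = ", "))
  structure(list(map = map[, c("marker", "chrom", "pos")],
                 chrom_lengths = chrom_lengths),
            class = "marker_map")
}

#' Read a marker map and chromosome lengths from TSV files
#'
#' @param map_path TSV with columns marker, chrom, pos.
#' @param lengths_path TSV with columns chrom, length.
#' @return a [marker_map].
#' @export
read_marker_map <- function(map_path, lengths_path) {
  mp <- utils::read.delim(map_path, header = TRUE, check.names = FALSE)
  names(mp)[1:3] <- c("marker", "chrom", "pos")
  ln <- utils::read.delim(lengths_path, header = TRUE, check.names = FALSE)
  marker_map(mp, stats::setNames(as.numeric(ln[[2L]]), as.character(ln[[1L]])))
}

map_lookup <- function(map, marker_ids, require_all = TRUE) {
  idx <- match(marker_ids, map$map$marker)
  if (require_all && anyNA(idx))
    stop("unmapped marker(s): ",
         paste(utils::head(marker_ids[is.na(idx)], 10L), collapse = ", "))
  list(chrom = map$map$chrom[idx], pos = map$map$pos[idx], idx = idx)
}

#' Filter markers on minor allele frequency
#'
#' The allele frequency is computed among the candidate fathers only,
#' with missing dosages excluded from the denominator:
#' freq = sum(a_ik) / (2 * number of non-missing fathers). Markers with
#' `min(freq, 1 - freq) >= maf_min` are kept; input order is preserved.
#'
#' @param panel a [genotype_panel].
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @return the filtered [genotype_panel].
#' @export
filter_maf <- function(panel, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  nn <- rowSums(!is.na(panel$dosages))
  freq <- rowSums(panel$dosages, na.rm = TRUE) / (2 * nn)
  maf <- pmin(freq, 1 - freq)
  keep <- !is.na(maf) & maf >= maf_min
  if (!any(keep)) {
    stop("all markers removed by maf filter (maf_min=", maf_min,
         "); maf quartiles: ",
         paste(signif(stats::quantile(maf, na.rm = TRUE), 3), collapse = " "))
  }
  subset_markers(panel, which(keep))
}

#' Prune markers on physical spacing and windowed LD
#'
#' Scans each chromosome in (position, marker id) order and, mimicking a
#' PLINK-style windowed pass, (1) removes the later marker of any pair of
#' consecutive retained markers closer than `min_bp`, then (2) removes any
#' marker whose squared Pearson correlation of dosages (pairwise complete
#' over non-missing fathers) with one of the previous `window - 1` *retained*
#' loci exceeds `r2_max`. Deterministic, single pass, idempotent.
#'
#' @param panel a [genotype_panel]; every marker must be mapped.
#' @param map a [marker_map].
#' @param window number of adjacent retained loci forming the LD window.
#' @param r2_max maximum allowed squared correlation within the window.
#' @param min_bp minimum physical distance between retained loci.
#' @return the pruned [genotype_panel], markers in original panel order.
#' @export
prune_spacing_ld <- function(panel, map, window = 50L, r2_max = 0.5,
                             min_bp = 10000) {
  lk <- map_lookup(map, panel$marker_ids)
  ord <- order(lk$chrom, lk$pos, panel$marker_ids)
  keep <- logical(n_markers(panel))
  for (chr in unique(lk$chrom[ord])) {
    idx <- ord[lk$chrom[ord] == chr]
    kept <- integer(0)
    for (k in idx) {
      if (length(kept)) {
        if (lk$pos[k] - lk$pos[kept[length(kept)]] < min_bp) next
        win <- kept[seq.int(max(1L, length(kept) - window + 2L), length(kept))]
        r <- suppressWarnings(
          stats::cor(panel$dosages[k, ], t(panel$dosages[win, , drop = FALSE]),
                     use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0
        if (any(r^2 > r2_max)) next
      }
      kept <- c(kept, k)
    }
    keep[kept] <- TRUE
  }
  if (!any(keep)) stop("all markers removed by spacing/LD pruning")
  subset_markers(panel, which(keep))
}

#' Export genotypes in Cervus CSV layout
#'
#' Writes the selected loci for (a) candidate fathers plus the mother and
#' (b) offspring, as CSV files with a leading `ID` column and two columns
#' per locus (`<locus>a`, `<locus>b`), alleles coded A/B from the oriented
#' dosage (0 = A,A; 1 = A,B; 2 = B,B; missing = *,*), plus a plain list of
#' candidate father ids. This is the hand-off point to external
#' likelihood-based parentage software.
#'
#' @param panel a [genotype_panel].
#' @param offspring an [offspring_set] or `NULL` to skip the offspring file.
#' @param solution a [marker_solution] whose markers are all in the panel.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_cervus <- function(panel, offspring, solution, out_dir) {
  loci <- solution$selected
  if (!length(loci)) stop("empty marker solution: nothing to export")
  if (!all(loci %in% panel$marker_ids))
    stop("solution markers missing from panel")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  code <- function(dos_mat, ids) {
    # dos_mat: loci x individuals
    a1 <- ifelse(is.na(dos_mat), "*", ifelse(dos_mat >= 1, "B", "A"))
    a2 <- ifelse(is.na(dos_mat), "*", ifelse(dos_mat == 2, "B", "A"))
    # interleave per-locus allele pairs; alphabetic pair order (A before B)
    out <- matrix("", nrow = ncol(dos_mat), ncol = 2L * nrow(dos_mat))
    out[, seq(1L, by = 2L, length.out = nrow(dos_mat))] <- t(a2)
    out[, seq(2L, by = 2L, length.out = nrow(dos_mat))] <- t(a1)
    colnames(out) <- as.vector(rbind(paste0(rownames(dos_mat), "a"),
                                     paste0(rownames(dos_mat), "b")))
    data.frame(ID = ids, out, check.names = FALSE)
  }

  sel <- panel$dosages[loci, , drop = FALSE]
  mom <- matrix(0L, length(loci), 1L, dimnames = list(loci, panel$maternal_id))
  parents <- code(cbind(sel, mom), c(panel$individual_ids, panel$maternal_id))
  f_parents <- file.path(out_dir, "cervus_candidates.csv")
  utils::write.csv(parents, f_parents, row.names = FALSE, quote = FALSE)

  f_list <- file.path(out_dir, "cervus_father_list.txt")
  writeLines(panel$individual_ids, f_list)

  paths <- c(candidates = f_parents, father_list = f_list)
  if (!is.null(offspring)) {
    off <- offspring$dosages[loci, , drop = FALSE]
    f_off <- file.path(out_dir, "cervus_offspring.csv")
    utils::write.csv(code(off, offspring$offspring_ids), f_off,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, offspring = f_off)
  }
  invisible(paths)
}
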