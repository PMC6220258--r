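# Standard-format I/O: phased VCF 4.2 with annotation INFO keys, BED
# (0-based half-open), TSV side tables and a JSON manifest.

#' Write a cohort as a phased VCF 4.2 file
#'
#' Genotypes are written phased (`a|b`); missing dosages become `./.`.
#' Annotations, when given, are carried as INFO keys `CSQ_CLASS`, `LOF`,
#' `CADD`, `EIGEN`, `EIGENPC`, `AA`, `MAPPABILITY` and `REGFEAT`.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @param annotations optional data.frame from [simulate_annotations()].
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, annotations = NULL) {
  m <- length(cohort$positions_bp)
  n <- length(cohort$sample_ids)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", cohort$chrom),
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Most severe consequence class\">",
    "##INFO=<ID=LOF,Number=1,Type=String,Description=\"LoF confidence (HC/LC)\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD score\">",
    "##INFO=<ID=EIGEN,Number=1,Type=Float,Description=\"Eigen score\">",
    "##INFO=<ID=EIGENPC,Number=1,Type=Float,Description=\"EigenPC score\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=MAPPABILITY,Number=1,Type=Float,Description=\"Mappability score\">",
    "##INFO=<ID=REGFEAT,Number=1,Type=String,Description=\"Overlapping regulatory feature ids\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids), collapse = "\t"))
  aa <- ifelse(cohort$ancestral_is_ref, cohort$ref, cohort$alt)
  if (is.null(annotations)) {
    info <- sprintf("AA=%s", aa)
  } else {
    info <- sprintf("CSQ_CLASS=%s;LOF=%s;CADD=%.4f;EIGEN=%.4f;EIGENPC=%.4f;AA=%s;MAPPABILITY=%.4f",
                    annotations$consequence, annotations$lof,
                    annotations$cadd, annotations$eigen,
                    annotations$eigenpc, aa, annotations$mappability)
    has_reg <- annotations$regulatory != ""
    info[has_reg] <- paste0(info[has_reg], ";REGFEAT=",
                            annotations$regulatory[has_reg])
  }
  H <- cohort$haplotypes
  odd <- seq(1L, 2L * n, by = 2L)
  # m x n genotype strings
  gt <- matrix(paste(H[odd, , drop = FALSE], H[odd + 1L, , drop = FALSE],
                     sep = "|"),
               nrow = n, ncol = m, byrow = FALSE)
  gt[is.na(cohort$dosages)] <- "./."
  body <- paste(cohort$chrom, cohort$positions_bp, cohort$variant_ids,
                cohort$ref, cohort$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased VCF into a cohort (and annotations)
#'
#' Reads a VCF written by [write_cohort_vcf()] (or any biallelic phased VCF
#' carrying the same INFO keys) via `vcfR`.
#'
#' @param path VCF path.
#' @param recomb_rate cM/Mb used to reconstruct cM positions when no map is
#'   supplied.
#' @param cM_map optional data.frame (pos_bp, cM) for interpolated positions.
#' @return list with `cohort` and `annotations` (NULL if the INFO keys are
#'   absent).
#' @export
read_cohort_vcf <- function(path, recomb_rate = 1, cM_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  m <- nrow(fix)
  gt <- v@gt[, -1, drop = FALSE]
  n <- ncol(gt)
  H <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  D <- matrix(NA_integer_, nrow = n, ncol = m)
  a1i <- matrix(suppressWarnings(as.integer(substr(gt, 1L, 1L))),
                nrow = m, ncol = n)
  a2i <- matrix(suppressWarnings(as.integer(substr(gt, 3L, 3L))),
                nrow = m, ncol = n)
  for (i in seq_len(n)) {
    H[2L * i - 1L, ] <- a1i[, i]
    H[2L * i, ] <- a2i[, i]
    D[i, ] <- a1i[, i] + a2i[, i]
  }
  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (all(is.na(x))) NULL else x
  }
  aa <- info_get("AA")
  ref <- unname(fix[, "REF"]); alt <- unname(fix[, "ALT"])
  anc_ref <- if (is.null(aa)) rep(TRUE, m) else aa == ref
  pos_bp <- as.integer(fix[, "POS"])
  pos_cM <- if (is.null(cM_map)) pos_bp * recomb_rate / 1e6 else
    stats::approx(cM_map$pos_bp, cM_map$cM, xout = pos_bp, rule = 2)$y
  cohort <- structure(list(
    haplotypes = H, dosages = D, chrom = unname(fix[1, "CHROM"]),
    positions_bp = pos_bp, positions_cM = pos_cM,
    ref = ref, alt = alt, ancestral_is_ref = anc_ref,
    variant_ids = unname(fix[, "ID"]), sample_ids = colnames(gt)
  ), class = "cohort")
  csq <- info_get("CSQ_CLASS")
  annotations <- NULL
  if (!is.null(csq)) {
    reg <- info_get("REGFEAT")
    reg <- if (is.null(reg)) character(m) else ifelse(is.na(reg), "", reg)
    annotations <- data.frame(
      variant_id = cohort$variant_ids,
      consequence = csq,
      lof = info_get("LOF") %||% rep("none", m),
      cadd = as.numeric(info_get("CADD") %||% rep(NA, m)),
      eigen = as.numeric(info_get("EIGEN") %||% rep(NA, m)),
      eigenpc = as.numeric(info_get("EIGENPC") %||% rep(NA, m)),
      mappability = as.numeric(info_get("MAPPABILITY") %||% rep(NA, m)),
      regulatory = reg, stringsAsFactors = FALSE)
  }
  list(cohort = cohort, annotations = annotations)
}

#' Write a complete fixture set for a synthetic cohort
#'
#' Emits the phased VCF (annotations as INFO fields), exon and regulatory
#' BED files (0-based half-open), the eQTL link TSV, the trait TSV, a cM map
#' TSV and a JSON manifest of the generating parameters. The set round-trips
#' losslessly through [read_cohort_vcf()].
#'
#' @param cohort a `cohort`.
#' @param annotations annotation data.frame.
#' @param gene_models list from [simulate_gene_models()].
#' @param traits named vector, or data.frame with sample_id plus trait
#'   columns.
#' @param outdir output directory (created if missing).
#' @param manifest optional list of true generating parameters to record.
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(cohort, annotations, gene_models, traits,
                              outdir, manifest = list()) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
  }
  paths <- c(
    vcf = file.path(outdir, "cohort.vcf"),
    exons_bed = file.path(outdir, "exons.bed"),
    regulatory_bed = file.path(outdir, "regulatory.bed"),
    eqtl_tsv = file.path(outdir, "eqtl_links.tsv"),
    traits_tsv = file.path(outdir, "traits.tsv"),
    cm_map_tsv = file.path(outdir, "cm_map.tsv"),
    manifest_json = file.path(outdir, "manifest.json"))
  write_cohort_vcf(cohort, paths["vcf"], annotations)
  utils::write.table(
    data.frame(chrom = cohort$chrom, start = gene_models$exons$start,
               end = gene_models$exons$end, name = gene_models$exons$gene_id),
    paths["exons_bed"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    data.frame(chrom = cohort$chrom, start = gene_models$features$start,
               end = gene_models$features$end,
               name = gene_models$features$feature_id),
    paths["regulatory_bed"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(gene_models$eqtl, paths["eqtl_tsv"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- if (is.data.frame(traits)) traits else
    data.frame(sample_id = names(traits), trait = unname(traits))
  utils::write.table(tr, paths["traits_tsv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(pos_bp = cohort$positions_bp, cM = cohort$positions_cM),
    paths["cm_map_tsv"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, paths["manifest_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Read a BED file of named intervals
#' @param path BED path (chrom, start, end, name; 0-based half-open).
#' @param name_as column name for the 4th field (`"gene_id"` or
#'   `"feature_id"`).
#' @return data.frame with the name column, `start`, `end`.
#' @export
read_bed <- function(path, name_as = "gene_id") {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  out <- data.frame(name = x[[4]], start = x[[2]], end = x[[3]],
                    stringsAsFactors = FALSE)
  names(out)[1] <- name_as
  out
}

#' Export a kinship matrix
#'
#' Writes either the square matrix or the long (id1, id2, value) format.
#' @param kin a `kinship_matrix` (or plain matrix).
#' @param path output TSV path.
#' @param format `"long"` or `"square"`.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path, format = c("long", "square")) {
  format <- match.arg(format)
  K <- if (inherits(kin, "kinship_matrix")) kin$matrix else kin
  ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
  if (format == "square") {
    utils::write.table(K, path, sep = "\t", quote = FALSE,
                       row.names = ids, col.names = ids)
  } else {
    idx <- which(upper.tri(K, diag = TRUE), arr.ind = TRUE)
    utils::write.table(
      data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                 value = K[idx]),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
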