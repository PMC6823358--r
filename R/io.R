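# Plain-text interchange formats. All coordinates are 1-based inclusive,
# including SEG-like segment tables (documented difference from BED).

#' Read/write the 12-column variant TSV
#'
#' Columns: sample_id, component_id, chrom, pos, ref, alt, variant_class,
#' gene, protein_change, consequence, vaf, depth (plus any extra columns,
#' which are preserved).
#'
#' @param path File path.
#' @param variants Variant data frame.
#' @return \code{read_variant_tsv}: data frame; writers return the path
#'   invisibly.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  check_variant_frame(df, path)
  df
}

#' @rdname read_variant_tsv
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write SEG-like segment tables
#'
#' Columns: sample_id, chrom, start, end, log2_ratio, integer_cn, baf
#' (optional). Intervals are 1-based inclusive.
#'
#' @param path File path.
#' @param segments Segment data frame.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio", "integer_cn")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(path, " lacks required SEG columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$start > df$end)) stop(path, ": segment start exceeds end")
  df
}

#' @rdname read_seg
#' @export
write_seg <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a numeric matrix TSV (row names in the first column)
#'
#' @param path File path.
#' @param mat Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-sample somatic VCF into the variant table
#'
#' Minimal VCF 4.2 support via the vcfR parser: the tumor sample column must
#' carry AD (ref,alt depths) or DP+AF to populate depth and VAF; gene,
#' protein change and consequence are taken from INFO keys GENE, AA and CSQ
#' when present.
#'
#' @param path VCF path (uncompressed or gzipped).
#' @param sample_id Sample identifier to stamp on the rows.
#' @return Variant data frame.
#' @export
read_variant_vcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop(path, ": FORMAT field AD required")
  ad1 <- ad[, 1L]
  ref_alt <- do.call(rbind, strsplit(ad1, ","))
  ref_d <- as.numeric(ref_alt[, 1L]); alt_d <- as.numeric(ref_alt[, 2L])
  depth <- ref_d + alt_d
  info_get <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  mq <- suppressWarnings(as.numeric(info_get("MQ")))
  mq[is.na(mq)] <- 60
  out <- data.frame(
    sample_id = sample_id, component_id = "bulk", chrom = fix$CHROM,
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    variant_class = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L,
                           "SNV", "indel"),
    gene = info_get("GENE"), protein_change = info_get("AA"),
    consequence = info_get("CSQ"),
    vaf = ifelse(depth > 0, alt_d / depth, 0), depth = depth,
    mapping_quality = mq, origin = "somatic", stringsAsFactors = FALSE
  )
  out
}

#' Pipeline configuration file (YAML)
#'
#' Reads a YAML configuration, fills defaults for absent keys and rejects
#' unknown keys. Recognized keys: seed, out_dir, recurrence_threshold,
#' aberration_threshold, cnh_count_threshold, clonal_cutoff, hyper_cutoff,
#' consensus_reps, consensus_k.
#'
#' @param path YAML file path (NULL for all defaults).
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L, out_dir = "results", recurrence_threshold = 2L,
    aberration_threshold = 0.3, cnh_count_threshold = 8L,
    clonal_cutoff = 0.8, hyper_cutoff = 0.4, consensus_reps = 1000L,
    consensus_k = 2:5
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, user)
}

#' Write a provenance record for a pipeline run
#'
#' Machine-readable YAML with the package version, seed, settings and a
#' content checksum of the settings, for auditability of each output set.
#'
#' @param path Output path.
#' @param config Settings list.
#' @param seed Seed used.
#' @export
write_provenance <- function(path, config, seed) {
  cfg_text <- yaml::as.yaml(config)
  checksum <- sum(utf8ToInt(cfg_text) * seq_len(nchar(cfg_text))) %% 2147483647
  yaml::write_yaml(list(
    package = "csgenomics",
    version = as.character(utils::packageVersion("csgenomics")),
    seed = seed, config_checksum = checksum, config = config
  ), path)
  invisible(path)
}
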