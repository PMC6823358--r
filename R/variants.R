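#' Canonical variant key
#'
#' Variants are keyed on (chrom, pos, ref, alt) throughout the pipeline:
#' caller consensus, cohort recurrence, trunk/branch partitioning and the
#' multi-region presence matrix all match on this exact-allele key.
#'
#' @param variants Data frame with columns chrom, pos, ref, alt.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

required_variant_cols <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "variant_class", "gene",
  "protein_change", "consequence", "vaf", "depth", "mapping_quality"
)

check_variant_frame <- function(variants, context = "variant table") {
  missing <- setdiff(required_variant_cols, names(variants))
  if (length(missing)) {
    stop(context, " lacks required columns: ", paste(missing, collapse = ", "))
  }
  invisible(variants)
}

#' Merge per-caller somatic variant calls by 2-of-3 consensus
#'
#' A variant is taken as genuine when it is detected by at least two of the
#' callers (exact-allele key). VAF and depth of a retained variant are the
#' medians across its supporting callers; the \code{callers} column records
#' the supporters. All other annotation is taken from the first supporting
#' caller in list order.
#'
#' @param calls_per_caller Named list (1-3 elements) of variant data frames,
#'   one per caller.
#' @param min_support Minimum number of supporting callers (default 2).
#' @return A variant data frame restricted to consensus calls.
#' @export
consensus_merge <- function(calls_per_caller, min_support = 2L) {
  stopifnot(is.list(calls_per_caller), length(calls_per_caller) >= 1L,
            length(calls_per_caller) <= 3L)
  caller_names <- names(calls_per_caller)
  if (is.null(caller_names) || any(!nzchar(caller_names))) {
    stop("calls_per_caller must be a named list (one name per caller)")
  }
  for (nm in caller_names) {
    df <- calls_per_caller[[nm]]
    if (nrow(df) == 0L) next
    check_variant_frame(df, paste0("caller table '", nm, "'"))
    k <- variant_key(df)
    if (anyDuplicated(k)) {
      stop("duplicate variant key within one caller: ", k[duplicated(k)][1L])
    }
  }
  combined <- do.call(rbind, lapply(caller_names, function(nm) {
    df <- calls_per_caller[[nm]]
    if (nrow(df) == 0L) return(NULL)
    df$.caller <- nm
    df
  }))
  if (is.null(combined) || nrow(combined) == 0L) {
    out <- calls_per_caller[[1L]][0, , drop = FALSE]
    out$callers <- character(0)
    return(out)
  }
  key <- variant_key(combined)
  support <- table(key)
  keep_keys <- names(support)[support >= min_support]
  sel <- key %in% keep_keys
  combined <- combined[sel, , drop = FALSE]
  key <- key[sel]
  ord <- order(key)
  combined <- combined[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- combined[first, , drop = FALSE]
  out$vaf <- as.numeric(tapply(combined$vaf, key, stats::median)[key[first]])
  out$depth <- as.numeric(tapply(combined$depth, key, stats::median)[key[first]])
  out$callers <- as.character(tapply(combined$.caller, key, function(x) {
    paste(x, collapse = ",")
  })[key[first]])
  out$.caller <- NULL
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count cohort recurrence of variant keys
#'
#' @param variants Combined variant data frame across samples (columns
#'   sample_id, chrom, pos, ref, alt).
#' @return Named integer vector: key -> number of distinct samples carrying it.
#' @export
cohort_recurrence_counts <- function(variants) {
  if (nrow(variants) == 0L) return(stats::setNames(integer(0), character(0)))
  k <- variant_key(variants)
  tab <- tapply(variants$sample_id, k, function(s) length(unique(s)))
  stats::setNames(as.integer(tab), names(tab))
}

# Longest homopolymer run adjacent to the center of a reference context
# window. "Adjacent": a run of identical bases whose span comes within 1 bp
# of the variant position (the window center).
homopolymer_adjacent <- function(context, min_run = 5L) {
  n <- nchar(context)
  center <- (n + 1L) %/% 2L
  bases <- strsplit(toupper(context), "")[[1L]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$lengths >= min_run & r$values %in% c("A", "C", "G", "T"))
  for (i in long) {
    if (starts[i] <= center + 1L && ends[i] >= center - 1L) return(TRUE)
  }
  FALSE
}

#' Length-weighted modal chromosome copy number
#'
#' A chromosome is called aneuploid when its modal integer copy number,
#' weighted by segment length, differs from 2. Chromosomes with no segments
#' are treated as diploid.
#'
#' @param segments Segment data frame (chrom, start, end, integer_cn).
#' @return Named integer vector: chromosome -> modal copy number.
#' @export
chrom_modal_ploidy <- function(segments) {
  if (nrow(segments) == 0L) return(stats::setNames(integer(0), character(0)))
  out <- tapply(seq_len(nrow(segments)), segments$chrom, function(i) {
    len <- segments$end[i] - segments$start[i] + 1
    w <- tapply(len, segments$integer_cn[i], sum)
    as.integer(names(w)[which.max(w)])
  })
  stats::setNames(as.integer(out), names(out))
}

#' Remove FFPE sequencing-noise artifacts
#'
#' Applies five independent removal criteria; the result is the set of
#' variants surviving all of them, so the order of application is immaterial:
#' \enumerate{
#'   \item mapping quality < 30;
#'   \item read depth < 50 (depth exactly 50 is retained);
#'   \item indels adjacent to a homopolymer run of 5 or more identical bases
#'     (a \code{context} column with the +/-6 bp reference window around the
#'     variant is required for indels);
#'   \item variant keys recurrent in \code{recurrence_threshold} or more
#'     cohort samples and absent from the whitelist of database-recurrent
#'     keys;
#'   \item variants on aneuploid chromosomes (modal copy number != 2).
#' }
#'
#' @param variants Variant data frame.
#' @param cohort_recurrence Named integer vector from
#'   \code{\link{cohort_recurrence_counts}}, or NULL to skip criterion 4.
#' @param whitelist Character vector of variant keys exempt from criterion 4.
#' @param chrom_ploidy Named integer vector (chromosome -> modal copy number),
#'   or NULL to skip criterion 5; chromosomes not named are treated as diploid.
#' @param recurrence_threshold Minimum number of samples for criterion 4
#'   (default 2).
#' @return Filtered variant data frame with a logical attribute-free result;
#'   per-criterion removal counts are attached as attribute
#'   \code{"filter_counts"} for audit logging.
#' @export
apply_ffpe_filters <- function(variants, cohort_recurrence = NULL,
                               whitelist = character(0), chrom_ploidy = NULL,
                               recurrence_threshold = 2L) {
  check_variant_frame(variants)
  n <- nrow(variants)
  if (n == 0L) return(variants)
  keys <- variant_key(variants)

  fail_mq <- variants$mapping_quality < 30
  fail_depth <- variants$depth < 50

  is_indel <- variants$variant_class == "indel"
  fail_hp <- rep(FALSE, n)
  if (any(is_indel)) {
    ctx <- if ("context" %in% names(variants)) variants$context else rep(NA_character_, n)
    missing_ctx <- is_indel & (is.na(ctx) | !nzchar(ctx))
    if (any(missing_ctx)) {
      stop("missing reference context for indel(s): ",
           paste(utils::head(keys[missing_ctx], 3L), collapse = ", "))
    }
    fail_hp[is_indel] <- vapply(ctx[is_indel], homopolymer_adjacent, logical(1))
  }

  fail_rec <- rep(FALSE, n)
  if (!is.null(cohort_recurrence)) {
    rec <- cohort_recurrence[keys]
    rec[is.na(rec)] <- 0L
    fail_rec <- rec >= recurrence_threshold & !(keys %in% whitelist)
  }

  fail_aneu <- rep(FALSE, n)
  if (!is.null(chrom_ploidy)) {
    pl <- chrom_ploidy[variants$chrom]
    pl[is.na(pl)] <- 2L
    fail_aneu <- pl != 2L
  }

  keep <- !(fail_mq | fail_depth | fail_hp | fail_rec | fail_aneu)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    input = n, low_mapping_quality = sum(fail_mq), shallow_depth = sum(fail_depth),
    homopolymer_indel = sum(fail_hp), cohort_recurrent = sum(fail_rec),
    aneuploid_chrom = sum(fail_aneu), retained = sum(keep)
  )
  out
}

#' Filter germline variants to the significant set
#'
#' Keeps nonsynonymous variants with read depth > 20, variant read frequency
#' > 0.2 and global population minor allele frequency < 0.01.
#'
#' @param variants Germline variant data frame; must carry a
#'   \code{population_maf} column (0 when unknown).
#' @return Filtered data frame.
#' @export
filter_germline <- function(variants) {
  check_variant_frame(variants, "germline table")
  if (!"population_maf" %in% names(variants)) {
    stop("germline table lacks population_maf column")
  }
  keep <- variants$consequence != "synonymous" &
    variants$depth > 20 &
    variants$vaf > 0.2 &
    variants$population_maf < 0.01
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loss-of-heterozygosity call from variant read frequency
#'
#' Loss of the wildtype allele is called when the variant read frequency
#' strictly exceeds 0.6.
#'
#' @param vaf Numeric vector of variant read frequencies in \[0, 1\].
#' @return Logical vector.
#' @export
call_loh <- function(vaf) {
  stopifnot(is.numeric(vaf))
  vaf > 0.6
}
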