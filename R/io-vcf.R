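#' Construct a variant-record table
#'
#' The package's in-memory representation of one single-sample callset: a
#' data.frame with one row per biallelic call carrying the site annotations
#' the hard filters consume (DP, MQ0, QD, HRun, SB, QUAL), the genotype, the
#' variant class and the filter status. Missing annotations are `NA`.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param id Marker identifiers; `NA` for novel sites. A non-`NA` id encodes
#'   dbSNP membership.
#' @param ref,alt Allele strings over `A`,`C`,`G`,`T`.
#' @param qual Phred-scaled site quality (QUAL).
#' @param genotype Genotype states (see [genotype_states()]).
#' @param depth Read depth (DP); `mq0` count of mapping-quality-zero reads;
#'   `qd` quality by depth; `hrun` homopolymer run length; `sb` strand bias.
#' @param vclass `"SNP"` or `"INDEL"`; defaults to SNP iff both alleles are
#'   single bases.
#' @param filter `"PASS"` or semicolon-joined failed filter names; `"."` for
#'   not-yet-filtered.
#' @return data.frame of class `variant_records`.
#' @export
variant_records <- function(chrom, pos, ref, alt, genotype,
                            id = NA_character_, qual = NA_real_,
                            depth = NA_integer_, mq0 = NA_integer_,
                            qd = NA_real_, hrun = NA_real_, sb = NA_real_,
                            vclass = NULL, filter = ".") {
  n <- length(pos)
  if (is.null(vclass)) {
    vclass <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
  }
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    id = rep_len(as.character(id), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    qual = rep_len(as.numeric(qual), n),
    depth = rep_len(as.integer(depth), n),
    mq0 = rep_len(as.integer(mq0), n),
    qd = rep_len(as.numeric(qd), n),
    hrun = rep_len(as.numeric(hrun), n),
    sb = rep_len(as.numeric(sb), n),
    genotype = rep_len(as.character(genotype), n),
    vclass = rep_len(as.character(vclass), n),
    filter = rep_len(as.character(filter), n),
    stringsAsFactors = FALSE
  )
  validate_variant_records(df)
  class(df) <- c("variant_records", "data.frame")
  df
}

validate_variant_records <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  stopifnot(
    all(df$pos >= 1L),
    all(df$ref != df$alt),
    all(df$genotype %in% genotype_states()),
    all(df$vclass %in% c("SNP", "INDEL"))
  )
  is_snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  if (any(is_snp != (df$vclass == "SNP"))) {
    stop("vclass must be SNP iff ref and alt are both single bases")
  }
  dp <- df$depth; m0 <- df$mq0
  ok <- is.na(dp) | dp >= 0L
  if (!all(ok)) stop("depth must be >= 0")
  both <- !is.na(dp) & !is.na(m0)
  if (any(both & (m0 < 0L | m0 > dp))) stop("mq0 must satisfy 0 <= mq0 <= depth")
  invisible(df)
}

# INFO keys the reader/writer round-trips, in canonical order.
.vcf_info_keys <- c(DP = "Integer", MQ0 = "Integer", QD = "Float",
                    HRun = "Integer", SB = "Float")

#' Read a single-sample VCF into a variant-record table
#'
#' Parses a VCF 4.1 file via `vcfR`, mapping each biallelic record of the
#' chosen sample to one row. Multi-allelic records are split into one row per
#' alternate allele sharing the position; the per-alternate genotype is the
#' allele's copy number (0 = HOM_REF, 1 = HET, 2 = HOM_ALT). Site annotations
#' are taken from the sample FORMAT fields when present, else from INFO;
#' missing annotations are stored as `NA`. A `./.` genotype maps to
#' `NO_CALL`, an ID of `.` to absent. Records whose alleles contain bases
#' outside `A`,`C`,`G`,`T` are dropped with a warning (count in attribute
#' `n_rejected_alleles`).
#'
#' @param path Path to a VCF file.
#' @param sample Sample name; default the first sample column.
#' @return A `variant_records` data.frame ordered as in the file.
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (length(samples) < 1L) stop("VCF has no sample column: ", path)
  if (is.null(sample)) sample <- samples[1L]
  if (!sample %in% samples) stop("unknown sample '", sample, "' in ", path)

  if (n == 0L) {
    out <- variant_records(character(0), integer(0), character(0),
                           character(0), character(0))
    attr(out, "n_rejected_alleles") <- 0L
    return(out)
  }

  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, n) else x
  }
  gt_raw <- v@gt[, sample]
  gt_field <- sub(":.*$", "", gt_raw)
  gt_field[is.na(gt_field)] <- "./."

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(n), n_alt)        # source record per output row
  which_alt <- sequence(n_alt)         # 1-based alternate index per row

  # per-alternate genotype from the allele indices in GT
  allele_mat <- t(vapply(strsplit(gt_field[idx], "[/|]"), function(a) {
    a <- suppressWarnings(as.integer(a))
    c(a, rep(NA_integer_, 2L))[1:2]
  }, integer(2)))
  copies <- rowSums(allele_mat == which_alt, na.rm = TRUE)
  no_call <- is.na(allele_mat[, 1L]) & is.na(allele_mat[, 2L])
  genotype <- ifelse(no_call, "NO_CALL",
                     c("HOM_REF", "HET", "HOM_ALT")[copies + 1L])

  ref <- fix[idx, "REF"]
  alt <- unlist(alts)  # idx is nondecreasing, so this is file order
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    id = ifelse(is.na(fix[idx, "ID"]) | fix[idx, "ID"] == ".",
                NA_character_, fix[idx, "ID"]),
    ref = ref,
    alt = alt,
    qual = num(fix[idx, "QUAL"]),
    depth = as.integer(num(info_get("DP")[idx])),
    mq0 = as.integer(num(info_get("MQ0")[idx])),
    qd = num(info_get("QD")[idx]),
    hrun = num(info_get("HRun")[idx]),
    sb = num(info_get("SB")[idx]),
    genotype = genotype,
    vclass = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL"),
    filter = ifelse(is.na(fix[idx, "FILTER"]), ".", fix[idx, "FILTER"]),
    stringsAsFactors = FALSE
  )
  ok <- grepl("^[ACGT]+$", df$ref) & grepl("^[ACGT]+$", df$alt)
  n_rej <- sum(!ok)
  if (n_rej > 0L) {
    warning(n_rej, " record(s) with non-ACGT alleles rejected in ", path)
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_variant_records(df)
  class(df) <- c("variant_records", "data.frame")
  attr(df, "n_rejected_alleles") <- n_rej
  df
}

#' Write a variant-record table as a single-sample VCF
#'
#' Emits a minimal valid VCF 4.1 with the annotations in INFO, the genotype
#' in the sample column, and the FILTER column populated from the record's
#' filter status (`PASS`, `.`, or semicolon-joined failed filter names).
#'
#' @param records A `variant_records` data.frame, sorted by (chrom, pos).
#' @param path Output path.
#' @param sample Sample name for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample = "SAMPLE") {
  df <- as.data.frame(records)
  if (nrow(df) > 0L && is.unsorted(order(df$chrom, df$pos))) {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
  }
  hdr <- c(
    "##fileformat=VCFv4.1",
    sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
            names(.vcf_info_keys), .vcf_info_keys, names(.vcf_info_keys)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  if (nrow(df) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  fmt_num <- function(x) {
    s <- vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      format(v, scientific = FALSE, trim = TRUE)
    }, "")
    # strip trailing zeros only after a decimal point ("100" stays "100")
    has_dec <- !is.na(s) & grepl(".", s, fixed = TRUE)
    s[has_dec] <- sub("\\.?0+$", "", s[has_dec])
    s
  }
  info_cols <- cbind(DP = as.character(df$depth), MQ0 = as.character(df$mq0),
                     QD = fmt_num(df$qd), HRun = fmt_num(df$hrun),
                     SB = fmt_num(df$sb))
  info <- apply(info_cols, 1L, function(r) {
    keep <- !is.na(r)
    if (!any(keep)) "." else paste(paste0(colnames(info_cols)[keep], "=", r[keep]),
                                   collapse = ";")
  })
  gt <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
          NO_CALL = "./.")[df$genotype]
  lines <- paste(df$chrom, df$pos,
                 ifelse(is.na(df$id), ".", df$id),
                 df$ref, df$alt,
                 ifelse(is.na(df$qual), ".", fmt_num(df$qual)),
                 ifelse(is.na(df$filter), ".", df$filter),
                 info, "GT", gt, sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
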