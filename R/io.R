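# Readers and writers for the pipeline's exchange formats.
# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based VCF convention happens only inside these functions.

#' Write gene models to BED and a feature TSV
#'
#' @param genes gene table from [simulate_genes()] (or with the same
#'   columns).
#' @param bed_path,tsv_path output paths; either may be `NULL` to skip.
#' @return invisibly, the written paths.
#' @export
write_genes <- function(genes, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- genes[, c("chrom", "start", "end", "gene_id")]
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    write.table(genes, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read gene models from a feature TSV
#'
#' @param tsv_path path written by [write_genes()].
#' @return gene `data.frame`.
#' @export
read_genes <- function(tsv_path) {
  read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write regions (introgressed or sweep) to BED
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` and optionally
#'   a name column (fourth BED field; defaults to `region_<i>`).
#' @param path output path.
#' @param name_col optional column to use as the BED name field.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, name_col = NULL) {
  name <- if (!is.null(name_col) && name_col %in% names(regions)) {
    regions[[name_col]]
  } else {
    sprintf("region_%d", seq_len(nrow(regions)))
  }
  bed <- data.frame(regions$chrom, regions$start, regions$end, name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED path (0-based half-open, at least 3 columns).
#' @return `data.frame` with `chrom`, `start`, `end` and `name` when
#'   present.
#' @export
read_regions_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (nrow(bed) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4L) names(bed)[4] <- "name"
  bed
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

#' Write SNP records as VCF 4.2
#'
#' Emits one record per SNP with INFO keys `AA` (ancestral allele),
#' `AFAFR`/`AFEUR`/`AFASN` (per-population derived-allele frequencies),
#' `NPEUR`/`NPASN` (marginal probabilities of Neanderthal ancestry), `SSC`
#' (selective-sweep S score) and flag keys `BEQTL`, `OPENCHROM`, `HISTENH`,
#' `DNASE`, plus unphased genotypes for the archaic samples `ALTAI` and
#' `DENISOVA` (missing genotypes as `./.`). The REF field carries the
#' ancestral allele, ALT the derived allele; POS is the internal 0-based
#' position plus one.
#'
#' @param snps SNP records (see [simulate_snps()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variants_vcf <- function(snps, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=selintro",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##INFO=<ID=AFAFR,Number=1,Type=Float,Description="Derived allele frequency, African">',
    '##INFO=<ID=AFEUR,Number=1,Type=Float,Description="Derived allele frequency, European">',
    '##INFO=<ID=AFASN,Number=1,Type=Float,Description="Derived allele frequency, East Asian">',
    '##INFO=<ID=NPEUR,Number=1,Type=Float,Description="Neanderthal ancestry probability, European">',
    '##INFO=<ID=NPASN,Number=1,Type=Float,Description="Neanderthal ancestry probability, East Asian">',
    '##INFO=<ID=SSC,Number=1,Type=Float,Description="Selective sweep scan S score">',
    '##INFO=<ID=BEQTL,Number=0,Type=Flag,Description="Brain eQTL">',
    '##INFO=<ID=OPENCHROM,Number=0,Type=Flag,Description="Open chromatin">',
    '##INFO=<ID=HISTENH,Number=0,Type=Flag,Description="Enhancer histone marks">',
    '##INFO=<ID=DNASE,Number=0,Type=Flag,Description="DNase hypersensitivity">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ALTAI", "DENISOVA"), collapse = "\t")
  )
  gt_code <- function(a1, a2, ref, alt) {
    ifelse(is.na(a1) | is.na(a2), "./.",
           paste(ifelse(a1 == ref, 0L, 1L), ifelse(a2 == ref, 0L, 1L),
                 sep = "/"))
  }
  info <- paste0(
    "AA=", snps$ancestral,
    ";AFAFR=", fmt_num(snps$af_AFR),
    ";AFEUR=", fmt_num(snps$af_EUR),
    ";AFASN=", fmt_num(snps$af_ASN),
    ";NPEUR=", fmt_num(snps$np_EUR),
    ";NPASN=", fmt_num(snps$np_ASN),
    ";SSC=", fmt_num(snps$s_score),
    ifelse(snps$brain_eqtl, ";BEQTL", ""),
    ifelse(snps$open_chromatin, ";OPENCHROM", ""),
    ifelse(snps$histone_enhancer, ";HISTENH", ""),
    ifelse(snps$dnase, ";DNASE", "")
  )
  body <- paste(snps$chrom, snps$pos + 1L, snps$snp_id,
                snps$ancestral, snps$derived, ".", "PASS", info, "GT",
                gt_code(snps$altai_a1, snps$altai_a2,
                        snps$ancestral, snps$derived),
                gt_code(snps$denisova_a1, snps$denisova_a2,
                        snps$ancestral, snps$derived),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SNP records from VCF or TSV
#'
#' VCF input is parsed with `vcfR`; positions are normalized to the
#' internal 0-based convention (`POS - 1`), alleles upper-cased and a
#' missing `AA` INFO key flags the ancestral state as missing (such SNPs
#' are excluded by polarity-dependent operations downstream). TSV input is
#' read back verbatim from [write_variants_tsv()] output.
#'
#' @param path input path.
#' @param dialect `"vcf"` or `"tsv"` (default: guessed from the
#'   extension).
#' @return SNP `data.frame` in the internal layout (see
#'   [simulate_snps()]; the `gene_id` column is absent for VCF input).
#' @export
read_variants <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (dialect == "tsv") {
    return(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  info_flag <- function(key) {
    grepl(paste0("(^|;)", key, "(;|$)"), fix$INFO)
  }
  aa <- toupper(vcfR::extract.info(v, element = "AA"))
  gt <- vcfR::extract.gt(v, element = "GT")
  decode_gt <- function(col, i) {
    g <- gt[, col]
    ref <- toupper(fix$REF)
    alt <- toupper(fix$ALT)
    a <- substr(g, 2 * i - 1, 2 * i - 1)
    out <- ifelse(a == "0", ref, ifelse(a == "1", alt, NA_character_))
    out[is.na(g) | g == "./."] <- NA_character_
    out
  }
  data.frame(
    snp_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ancestral = aa,
    derived = toupper(fix$ALT),
    af_AFR = info_num("AFAFR"),
    af_EUR = info_num("AFEUR"),
    af_ASN = info_num("AFASN"),
    np_EUR = info_num("NPEUR"),
    np_ASN = info_num("NPASN"),
    s_score = info_num("SSC"),
    altai_a1 = decode_gt("ALTAI", 1L),
    altai_a2 = decode_gt("ALTAI", 2L),
    denisova_a1 = decode_gt("DENISOVA", 1L),
    denisova_a2 = decode_gt("DENISOVA", 2L),
    brain_eqtl = info_flag("BEQTL"),
    open_chromatin = info_flag("OPENCHROM"),
    histone_enhancer = info_flag("HISTENH"),
    dnase = info_flag("DNASE"),
    stringsAsFactors = FALSE
  )
}

#' Write SNP records as TSV
#'
#' @param snps SNP records.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variants_tsv <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phased haplotype matrix as TSV
#'
#' Rows are chromosomes (including `ALTAI`/`DENISOVA`), columns SNP ids,
#' values 0/1.
#'
#' @param mat haplotype matrix (as produced by
#'   [plant_introgressed_haplotype()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hap_matrix <- function(mat, path) {
  df <- data.frame(chromosome = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased haplotype matrix written by [write_hap_matrix()]
#'
#' @param path input path.
#' @return integer matrix with chromosome rownames.
#' @export
read_hap_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  mat
}

#' Write the planted-truth record as JSON
#'
#' @param truth truth list from [simulate_cohort()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth record written by [write_truth_json()]
#'
#' @param path input path.
#' @return list.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
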