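# Readers and writers for the study's on-disk formats: VCF 4.2 genotypes
# (biallelic, GT only), sumstats TSV, gene coordinates TSV, abundance and
# covariate TSVs, PPI TSV, GMT, and a JSON truth manifest.

.write_vcf <- function(geno, snps, path) {
  n <- nrow(geno)
  stopifnot(ncol(geno) == nrow(snps))
  samples <- rownames(geno) %||% sprintf("S%04d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pleioscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[t(geno) + 1L], nrow = ncol(geno))
  fixed <- paste(snps$CHR, snps$BP, snps$SNP, snps$A2, snps$A1, ".",
                 "PASS", ".", "GT", sep = "\t")
  body <- do.call(paste, c(list(fixed), lapply(seq_len(n), function(s)
    gt[, s]), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a biallelic VCF into an A1 (ALT) dosage matrix
#'
#' @param path VCF file path.
#' @return List with `geno` (samples x SNPs 0/1/2 matrix) and `snps`
#'   (data.frame `SNP CHR BP A1 A2`, A1 = ALT allele, whose dosage is
#'   counted).
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  d <- (gt == "0/1" | gt == "1/0" | gt == "0|1" | gt == "1|0") +
    2L * (gt == "1/1" | gt == "1|1")
  geno <- t(d)
  colnames(geno) <- fix[, "ID"]
  list(
    geno = geno,
    snps = data.frame(
      SNP = fix[, "ID"], CHR = fix[, "CHROM"], BP = as.integer(fix[, "POS"]),
      A1 = fix[, "ALT"], A2 = fix[, "REF"], stringsAsFactors = FALSE
    )
  )
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expects columns `SNP A1 A2 Z N` with optional `CHR BP FREQ BETA SE`.
#'
#' @param path TSV path.
#' @return data.frame with validated columns.
#' @export
read_sumstats <- function(path) {
  ss <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("SNP", "A1", "A2", "Z", "N")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop_cfg("sumstats %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  if (anyDuplicated(ss$SNP)) stop_cfg("duplicate SNP ids in %s", path)
  if (any(!is.finite(ss$Z))) stop_cfg("non-finite z-scores in %s", path)
  if (any(ss$N < 2)) stop_cfg("N < 2 in %s", path)
  if (any(ss$A1 == ss$A2)) stop_cfg("A1 == A2 in %s", path)
  ss
}

#' Write / read GMT gene-set files
#'
#' @param sets Named list of character vectors (attribute `description`
#'   optional per element).
#' @param path GMT file path.
#' @return `write_gmt` the path; `read_gmt` a named list of character
#'   vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    members <- f[-(1:2)]
    attr(members, "description") <- f[2]
    out[[f[1]]] <- members
  }
  out
}

#' Read a PPI edge list (minimal BioGRID TAB3-style dialect)
#'
#' @param path TSV with columns `SYMBOL_A SYMBOL_B EVIDENCE_TYPE`.
#' @return data.frame of edges.
#' @export
read_ppi <- function(path) {
  e <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("SYMBOL_A", "SYMBOL_B", "EVIDENCE_TYPE")
  miss <- setdiff(need, names(e))
  if (length(miss))
    stop_cfg("PPI table %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  e
}

#' Write a complete synthetic study to a directory
#'
#' Emits panel and cohort VCFs, one sumstats TSV per trait, abundance,
#' covariate and gene-coordinate TSVs, the PPI TSV, annotation GMT and a
#' JSON truth manifest; every file round-trips through the module readers.
#'
#' @param study A study list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return data.frame manifest (`file`, `type`).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- study$genome$layout
  man <- list()
  add <- function(file, type) man[[length(man) + 1]] <<- data.frame(
    file = file, type = type, stringsAsFactors = FALSE)

  .write_vcf(study$genome$panel, lay$snps, file.path(dir, "panel.vcf"))
  add("panel.vcf", "vcf")
  .write_vcf(study$genome$cohort, lay$snps, file.path(dir, "cohort.vcf"))
  add("cohort.vcf", "vcf")

  for (tr in names(study$sumstats)) {
    f <- sprintf("sumstats_%s.tsv", tr)
    data.table::fwrite(study$sumstats[[tr]], file.path(dir, f), sep = "\t")
    add(f, "sumstats")
  }
  ab <- data.frame(SAMPLE = sprintf("S%04d", seq_len(nrow(study$abundance))),
                   study$abundance, check.names = FALSE)
  data.table::fwrite(ab, file.path(dir, "abundance.tsv"), sep = "\t")
  add("abundance.tsv", "abundance")
  cv <- data.frame(SAMPLE = ab$SAMPLE, study$covariates, check.names = FALSE)
  data.table::fwrite(cv, file.path(dir, "covariates.tsv"), sep = "\t")
  add("covariates.tsv", "covariates")
  data.table::fwrite(lay$genes[, c("GENE", "CHR", "START", "END")],
                     file.path(dir, "genes.tsv"), sep = "\t")
  add("genes.tsv", "genes")
  if (!is.null(study$ppi)) {
    data.table::fwrite(study$ppi, file.path(dir, "ppi.tsv"), sep = "\t")
    add("ppi.tsv", "ppi")
  }
  if (!is.null(study$annotations) && length(study$annotations)) {
    write_gmt(study$annotations, file.path(dir, "annotations.gmt"))
    add("annotations.gmt", "gmt")
  }
  truth <- study$truth
  tr_json <- list(
    traits = truth$traits, rg_matrix = truth$rg_matrix,
    pleiotropic_links = truth$pleiotropic_links,
    linkage_decoys = truth$linkage_decoys, trans_links = truth$trans_links,
    ppi_fold = truth$ppi_fold, ppi_set_a = truth$ppi_set_a,
    ppi_set_b = truth$ppi_set_b, seed = study$config$seed
  )
  jsonlite::write_json(tr_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  add("truth.json", "truth")
  man <- do.call(rbind, man)
  data.table::fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  man
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return List with `panel`, `cohort` (dosage lists from
#'   [read_vcf_dosage()]), `sumstats` (named list), `abundance` (matrix),
#'   `covariates`, `genes`, `ppi`, `annotations`, `truth`.
#' @export
read_study <- function(dir) {
  man <- as.data.frame(data.table::fread(file.path(dir, "manifest.tsv")))
  out <- list(sumstats = list())
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    switch(man$type[i],
      vcf = {
        slot <- sub("\\.vcf$", "", man$file[i])
        out[[slot]] <- read_vcf_dosage(f)
      },
      sumstats = {
        tr <- sub("^sumstats_(.*)\\.tsv$", "\\1", man$file[i])
        out$sumstats[[tr]] <- read_sumstats(f)
      },
      abundance = {
        ab <- as.data.frame(data.table::fread(f))
        rn <- ab$SAMPLE
        ab <- as.matrix(ab[, -1, drop = FALSE])
        rownames(ab) <- rn
        out$abundance <- ab
      },
      covariates = {
        cv <- as.data.frame(data.table::fread(f))
        out$covariates <- cv[, -1, drop = FALSE]
      },
      genes = out$genes <- as.data.frame(data.table::fread(f,
        colClasses = list(character = "CHR"))),
      ppi = out$ppi <- read_ppi(f),
      gmt = out$annotations <- read_gmt(f),
      truth = out$truth <- jsonlite::read_json(f, simplifyVector = TRUE)
    )
  }
  out
}
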