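#' Read per-variant genotypes from a VCF or a genotype matrix
#'
#' VCF input is parsed with the vcfR package: the genotype is the number
#' of ALT alleles in the `GT` field (so 0/0 -> 0, 0/1 -> 1, 1/1 -> 2);
#' `./.` or `.` become missing.  Multiallelic and non-diploid sites are
#' skipped with a warning.  TSV input is a variants x samples integer
#' matrix whose first column holds variant identifiers and whose header
#' row holds sample identifiers; cells must be 0, 1, 2 or `NA`.
#'
#' @param path path to a `.vcf` or tab-delimited file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param count_ref count REF instead of ALT alleles (flips every
#'   genotype `g` to `2 - g`; association statistics are invariant to
#'   this choice).
#' @return A list of class `"genotype_set"` with `genotypes`
#'   (variants x samples integer matrix, `NA` = missing), `variants`
#'   (data.frame with `id`, and `chrom`/`pos` for VCF input), and
#'   `samples` (character vector).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           count_ref = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  gs <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  if (count_ref) gs$genotypes <- 2L - gs$genotypes
  gs
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)   # CHROM POS ID REF ALT QUAL FILTER
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # count ALT alleles from a diploid GT string; "." components -> NA
  alt_count <- function(s) {
    if (is.na(s) || s == "." || s == "./." || s == ".|.") return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  geno <- apply(gt, c(1L, 2L), alt_count)
  bad_ploidy <- apply(gt, 1L, function(r) {
    any(vapply(r[!is.na(r)], function(s) {
      length(strsplit(s, "[/|]")[[1L]]) != 2L && s != "."
    }, logical(1L)))
  })
  if (any(bad_ploidy)) {
    warning(sum(bad_ploidy), " non-diploid site(s) skipped")
    geno <- geno[!bad_ploidy, , drop = FALSE]
    fix <- fix[!bad_ploidy, , drop = FALSE]
  }
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], ":", fix[miss_id, "POS"])
  rownames(geno) <- ids
  structure(list(genotypes = geno,
                 variants = data.frame(id = ids,
                                       chrom = fix[, "CHROM"],
                                       pos = as.integer(fix[, "POS"]),
                                       stringsAsFactors = FALSE),
                 samples = colnames(geno)),
            class = "genotype_set")
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("genotype TSV needs an ID column plus >= 1 sample")
  ids <- as.character(tab[[1L]])
  geno <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(geno)) stop("genotype TSV cells must be numeric 0/1/2 or NA")
  if (any(geno[!is.na(geno)] != round(geno[!is.na(geno)]))) {
    stop("non-integer genotype found: dosages are not supported")
  }
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) {
    stop("genotype codes must be 0/1/2 or NA; first bad value at variant ",
         ids[which(bad, arr.ind = TRUE)[1L, 1L]])
  }
  rownames(geno) <- ids
  structure(list(genotypes = geno,
                 variants = data.frame(id = ids, stringsAsFactors = FALSE),
                 samples = colnames(geno)),
            class = "genotype_set")
}

#' Write a genotype matrix as TSV
#'
#' Inverse of the TSV branch of [read_genotypes()].
#'
#' @param gs a `"genotype_set"` (or a bare variants x samples matrix with
#'   dimnames).
#' @param path output path.
#' @export
write_genotypes_tsv <- function(gs, path) {
  geno <- if (inherits(gs, "genotype_set")) gs$genotypes else gs
  out <- data.frame(variant = rownames(geno), geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype table
#'
#' Tab-delimited file whose first column holds sample identifiers and the
#' remaining columns numeric phenotypes (binary traits as 0/1).
#' Non-numeric cells become missing and the affected individuals are
#' dropped per variant at test time.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix with sample IDs as row names.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("phenotype TSV needs an ID column plus >= 1 phenotype")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in phenotype file")
  y <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(y) <- "double")
  rownames(y) <- ids
  y
}

#' Association scan of every variant against the phenotypes
#'
#' Runs the proportional-odds score test ([po_score_test()]) for each
#' variant after aligning samples by ID (intersection; phenotype row
#' order is irrelevant).  Optionally adds likelihood-ratio,
#' Cochran-Armitage trend and Pearson chi-square columns — the latter two
#' require a single binary phenotype.  Degenerate variants never abort
#' the scan; they are flagged in the `status` column.
#'
#' @param gs a `"genotype_set"` from [read_genotypes()], or a variants x
#'   samples genotype matrix with sample column names.
#' @param pheno phenotype matrix with sample IDs as row names
#'   (see [read_phenotypes()]).
#' @param also character subset of `c("lrt", "trend", "chisq")` for extra
#'   test columns.
#' @param pseudo_inverse passed to [po_score_test()].
#' @param bonferroni add a Bonferroni-adjusted p-value column.
#' @return A data.frame with one row per variant: `variant`, `n_used`,
#'   `p0`, `p1`, `p2`, `statistic`, `df`, `p_value`, `status`, plus any
#'   requested extra columns.
#' @export
po_scan <- function(gs, pheno, also = character(),
                    pseudo_inverse = FALSE, bonferroni = FALSE) {
  geno <- if (inherits(gs, "genotype_set")) gs$genotypes else as.matrix(gs)
  if (length(also) > 0L) {
    also <- match.arg(also, c("lrt", "trend", "chisq"), several.ok = TRUE)
  }
  samples <- intersect(colnames(geno), rownames(pheno))
  if (length(samples) == 0L) stop("no overlapping sample IDs between genotypes and phenotypes")
  geno <- geno[, samples, drop = FALSE]
  pheno <- as.matrix(pheno)[samples, , drop = FALSE]

  is_binary <- ncol(pheno) == 1L && all(pheno[!is.na(pheno)] %in% c(0, 1))
  if (any(c("trend", "chisq") %in% also) && !is_binary) {
    stop("trend/chisq comparisons require a single binary (0/1) phenotype column")
  }

  rows <- lapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    st <- po_score_test(g, pheno, pseudo_inverse = pseudo_inverse)
    props <- if (is.null(st$fit)) rep(NA_real_, 3L) else st$fit$proportions
    row <- data.frame(variant = rownames(geno)[i], n_used = st$n_used,
                      p0 = props[1L], p1 = props[2L], p2 = props[3L],
                      statistic = st$statistic, df = st$df,
                      p_value = st$p.value, status = st$status,
                      stringsAsFactors = FALSE)
    if (st$status == "ok") {
      keep <- !is.na(g) & stats::complete.cases(pheno)
      if ("lrt" %in% also) {
        lr <- po_lrt(g[keep], pheno[keep, , drop = FALSE])
        row$lrt_statistic <- lr$statistic; row$lrt_p <- lr$p.value
      }
      if (any(c("trend", "chisq") %in% also)) {
        tab <- cc_table(g[keep], pheno[keep, 1L])
        if ("trend" %in% also) {
          tr <- tryCatch(trend_test(tab), error = function(e) NULL)
          row$trend_statistic <- if (is.null(tr)) NA_real_ else tr$statistic
          row$trend_p <- if (is.null(tr)) NA_real_ else tr$p.value
        }
        if ("chisq" %in% also) {
          cs <- tryCatch(pearson_chisq_test(tab), error = function(e) NULL)
          row$chisq_statistic <- if (is.null(cs)) NA_real_ else cs$statistic
          row$chisq_p <- if (is.null(cs)) NA_real_ else cs$p.value
        }
      }
    } else {
      for (nm in c(if ("lrt" %in% also) c("lrt_statistic", "lrt_p"),
                   if ("trend" %in% also) c("trend_statistic", "trend_p"),
                   if ("chisq" %in% also) c("chisq_statistic", "chisq_p"))) {
        row[[nm]] <- NA_real_
      }
    }
    row
  })
  res <- do.call(rbind, rows)
  if (bonferroni) {
    res$p_bonferroni <- stats::p.adjust(res$p_value, method = "bonferroni")
  }
  res
}

#' Write scan results as TSV
#'
#' @param res data.frame from [po_scan()].
#' @param path output path.
#' @export
write_scan_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
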