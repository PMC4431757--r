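#' SNP weight set for the genetic predisposition score
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param effect_allele single-base symbol per SNP (the BMI-increasing
#'   allele whose dosage is counted).
#' @param beta positive per-allele effect size from GWAS.
#' @return data frame of class \code{"snp_weight_set"} with columns
#'   \code{snp_id}, \code{effect_allele}, \code{beta}.
#' @export
snp_weight_set <- function(snp_id, effect_allele, beta) {
  snp_id <- as.character(snp_id)
  if (length(snp_id) < 1L) stop("at least one SNP weight is required")
  if (anyDuplicated(snp_id)) stop("duplicate snp_id in weight set")
  beta <- as.numeric(beta)
  if (any(!is.finite(beta) | beta <= 0)) stop("all beta coefficients must be > 0")
  if (length(effect_allele) != length(snp_id) || length(beta) != length(snp_id)) {
    stop("snp_id, effect_allele and beta must have equal length")
  }
  structure(
    data.frame(snp_id = snp_id, effect_allele = toupper(as.character(effect_allele)),
               beta = beta, stringsAsFactors = FALSE),
    class = c("snp_weight_set", "data.frame")
  )
}

#' Read / write SNP weights (TSV: snp_id, effect_allele, beta)
#' @param path file path.
#' @return \code{read_snp_weights}: a [snp_weight_set()].
#' @export
read_snp_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "effect_allele", "beta")
  if (!all(req %in% names(df))) {
    stop("weights TSV must have columns: ", paste(req, collapse = ", "))
  }
  snp_weight_set(df$snp_id, df$effect_allele, df$beta)
}

#' @rdname read_snp_weights
#' @param weights a [snp_weight_set()].
#' @export
write_snp_weights <- function(weights, path) {
  utils::write.table(as.data.frame(weights)[c("snp_id", "effect_allele", "beta")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a genotype dosage matrix with per-SNP QC metadata
#'
#' @param dosages numeric matrix, subjects x SNPs, entries in [0, 2]
#'   (effect-allele counts, possibly fractional after imputation) or NA for
#'   missing calls.  Column names are SNP ids.
#' @param maf optional per-SNP minor allele frequency; if omitted it is
#'   estimated from the observed dosages (allele frequency folded to
#'   [0, 0.5]).
#' @param call_rate optional per-SNP call rate; defaults to the observed
#'   fraction of non-missing dosages.
#' @return the matrix with class \code{"genotype_matrix"} and attributes
#'   \code{maf} and \code{call_rate} (named per SNP).
#' @export
genotype_matrix <- function(dosages, maf = NULL, call_rate = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) > 0L && is.null(colnames(dosages))) {
    stop("dosage matrix needs SNP ids as column names")
  }
  if (any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 2) stop("dosages must lie in [0, 2]")
  }
  if (is.null(call_rate)) {
    call_rate <- if (nrow(dosages) > 0L) colMeans(!is.na(dosages)) else
      rep(1, ncol(dosages))
  }
  if (is.null(maf)) {
    p <- if (nrow(dosages) > 0L) colMeans(dosages, na.rm = TRUE) / 2 else
      rep(0, ncol(dosages))
    maf <- pmin(p, 1 - p)
  }
  if (any(call_rate < 0 | call_rate > 1)) stop("call rate must lie in [0, 1]")
  if (any(maf < 0 | maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  structure(dosages,
            maf = stats::setNames(as.numeric(maf), colnames(dosages)),
            call_rate = stats::setNames(as.numeric(call_rate), colnames(dosages)),
            class = c("genotype_matrix", class(dosages)))
}

#' QC-filter SNPs on minor allele frequency and call rate
#'
#' Retains SNPs with \code{MAF >= maf_min} and
#' \code{call rate >= call_rate_min}; both thresholds follow the usual
#' array-QC convention (MAF below 0.5\% or call rate below 95\% excluded).
#' Column order is preserved; excluded ids are attached as attribute
#' \code{"excluded"}.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (fraction, default 0.005).
#' @param call_rate_min minimum call rate (fraction, default 0.95).
#' @return filtered [genotype_matrix()]; \code{attr(, "excluded")} lists the
#'   dropped SNP ids.
#' @export
qc_filter_snps <- function(geno, maf_min = 0.005, call_rate_min = 0.95) {
  stopifnot(inherits(geno, "genotype_matrix"))
  maf <- attr(geno, "maf"); cr <- attr(geno, "call_rate")
  keep <- maf >= maf_min & cr >= call_rate_min
  excluded <- colnames(geno)[!keep]
  if (length(excluded) == ncol(geno)) {
    warning("all SNPs failed QC; returning an empty genotype matrix")
  }
  out <- genotype_matrix(unclass(geno)[, keep, drop = FALSE],
                         maf = maf[keep], call_rate = cr[keep])
  attr(out, "excluded") <- excluded
  out
}

#' Extract effect-allele dosages from a VCF
#'
#' Reads GT (and, when present, the imputed-dosage DS field) for the SNPs
#' named in \code{weights}.  Dosage counts the effect allele: when the
#' effect allele is REF the ALT-count orientation is flipped (dosage =
#' 2 - ALT count).  Missing genotypes become NA and lower the SNP's call
#' rate; multiallelic records are skipped with a warning; weight SNPs
#' absent from the VCF are reported in attribute \code{"missing_snps"}.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or bgzipped).
#' @param weights a [snp_weight_set()].
#' @return a [genotype_matrix()] (subjects x retained SNPs).
#' @export
dosages_from_vcf <- function(vcf_path, weights) {
  stopifnot(inherits(weights, "snp_weight_set"))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  hit <- match(weights$snp_id, fix$ID)
  missing_snps <- weights$snp_id[is.na(hit)]
  found <- weights[!is.na(hit), , drop = FALSE]
  rows <- hit[!is.na(hit)]

  multi <- grepl(",", fix$ALT[rows])
  if (any(multi)) {
    warning("skipping multiallelic records: ",
            paste(found$snp_id[multi], collapse = ", "))
    rows <- rows[!multi]; found <- found[!multi, , drop = FALSE]
  }
  if (nrow(found) == 0L) stop("no requested biallelic SNPs found in VCF")

  gt <- vcfR::extract.gt(vcf, element = "GT")[rows, , drop = FALSE]
  ds <- if ("DS" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    suppressWarnings(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))[rows, , drop = FALSE]
  }

  alt_count <- function(g) {  # ALT dosage from a GT string, NA if any allele missing
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  dos <- t(apply(gt, 1L, function(row) vapply(row, alt_count, numeric(1L))))
  if (!is.null(ds)) {  # DS overrides hard calls where present
    dos[!is.na(ds)] <- ds[!is.na(ds)]
  }

  # orient to the effect allele
  ref <- fix$REF[rows]; alt <- fix$ALT[rows]
  eff_is_ref <- found$effect_allele == toupper(ref)
  eff_is_alt <- found$effect_allele == toupper(alt)
  if (any(!eff_is_ref & !eff_is_alt)) {
    stop("effect allele matches neither REF nor ALT for: ",
         paste(found$snp_id[!eff_is_ref & !eff_is_alt], collapse = ", "))
  }
  dos[eff_is_ref, ] <- 2 - dos[eff_is_ref, , drop = FALSE]

  out <- genotype_matrix(t(dos)[, seq_len(nrow(found)), drop = FALSE])
  colnames(out) <- found$snp_id
  # recompute metadata after the transpose/rename
  out <- genotype_matrix(unclass(out))
  attr(out, "missing_snps") <- missing_snps
  out
}

#' Weighted genetic predisposition score
#'
#' For \eqn{L} loci with effect-allele dosages \eqn{a_l \in [0, 2]} and
#' GWAS weights \eqn{\beta_l > 0}:
#' \deqn{GPS = \frac{\sum_l a_l \beta_l}{2 \sum_l \beta_l} \times 2L
#'           = L \frac{\sum_l a_l \beta_l}{\sum_l \beta_l},}
#' i.e. the \eqn{\beta}-weighted dosage sum rescaled so the score lives on
#' the allele-count scale \eqn{[0, 2L]} (0 = no effect alleles anywhere,
#' \eqn{2L} = homozygous for the effect allele at every locus).  Higher
#' scores indicate greater genetic predisposition to obesity.  With equal
#' weights the score reduces to the plain allele count.
#'
#' @param dosages numeric vector of length L, or a subjects x L matrix /
#'   [genotype_matrix()] (columns matched to \code{weights$snp_id} by name
#'   when named).
#' @param weights a [snp_weight_set()].
#' @param missing how to handle NA dosages: \code{"renormalize"} (default)
#'   rescales by the betas of the observed loci, keeping the [0, 2L] scale;
#'   \code{"fail"} raises an error.
#' @return numeric score(s) in [0, 2L].
#' @examples
#' w <- snp_weight_set(c("rs1", "rs2"), c("A", "G"), c(0.1, 0.3))
#' compute_gps(c(1, 2), w)  # 2 * (0.1 + 0.6) / 0.4 = 3.5
#' @export
compute_gps <- function(dosages, weights, missing = c("renormalize", "fail")) {
  missing <- match.arg(missing)
  stopifnot(inherits(weights, "snp_weight_set"))
  L <- nrow(weights)
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1L,
                                               dimnames = list(NULL, names(dosages)))
  A <- unclass(as.matrix(dosages))
  if (!is.null(colnames(A))) {
    idx <- match(weights$snp_id, colnames(A))
    if (any(is.na(idx))) {
      stop("dosage matrix lacks SNPs: ",
           paste(weights$snp_id[is.na(idx)], collapse = ", "))
    }
    A <- A[, idx, drop = FALSE]
  } else if (ncol(A) != L) {
    stop("unnamed dosage input must have exactly L = ", L, " columns")
  }
  if (any(A < 0 | A > 2, na.rm = TRUE) || any(is.infinite(A))) {
    stop("dosages must be finite and in [0, 2]")
  }
  beta <- weights$beta
  if (missing == "fail" && anyNA(A)) stop("missing dosages with missing = 'fail'")
  obs <- !is.na(A)
  num <- rowSums(sweep(A, 2L, beta, "*"), na.rm = TRUE)
  den <- obs %*% beta  # per-subject sum of betas over observed loci
  if (any(den == 0)) stop("a subject has no observed loci; GPS undefined")
  as.numeric(L * num / den)
}
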