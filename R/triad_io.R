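# Data model and file I/O for case-parent triad genotype data.
#
# A cohort holds three n_families x n_loci genotype matrices (mothers,
# fathers, children) coded 0/1/2 = copies of an analyst-designated allele,
# NA = missing, plus a locus annotation table. Which allele is designated is
# immaterial downstream: the fitness score is invariant to recoding g -> 2-g.

#' Construct a case-parent triad cohort
#'
#' Bundles the three genotype matrices of a case-parent triad study with a
#' locus annotation table, validating shapes, genotype codes, and Mendelian
#' consistency. Mendelian-impossible (mother, father, child) triples are
#' either masked to missing (with a warning giving the count) or rejected.
#'
#' @param mothers,fathers,children Integer matrices of dimension
#'   `n_families x n_loci` with entries 0, 1, 2 (copies of the designated
#'   allele) or `NA` for missing.
#' @param loci Data frame with columns `locus_id` (unique character),
#'   `chromosome` (non-empty character; loci with equal labels are treated as
#'   linked), and `position` (1-based integer, informational only).
#' @param family_ids Optional character vector of family identifiers; defaults
#'   to `fam1, fam2, ...`.
#' @param on_violation `"mask"` (default) replaces each Mendelian-inconsistent
#'   triple with `NA` for all three members at that locus and warns;
#'   `"error"` aborts instead.
#'
#' @return An object of class `triad_cohort`: a list with elements `mothers`,
#'   `fathers`, `children`, `loci`, `family_ids`, and attribute `n_masked`
#'   (count of masked triples).
#' @export
triad_cohort <- function(mothers, fathers, children, loci, family_ids = NULL,
                         on_violation = c("mask", "error")) {
  on_violation <- match.arg(on_violation)
  mothers <- as.matrix(mothers)
  fathers <- as.matrix(fathers)
  children <- as.matrix(children)
  if (!all(dim(mothers) == dim(fathers)) || !all(dim(mothers) == dim(children)))
    abort_validation("mother/father/child genotype matrices differ in shape")
  n_fam <- nrow(mothers)
  n_loci <- ncol(mothers)

  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("locus_id", "chromosome", "position")
  if (!all(req %in% names(loci)))
    abort_validation("locus annotation needs columns: ", paste(req, collapse = ", "))
  loci$locus_id <- as.character(loci$locus_id)
  loci$chromosome <- as.character(loci$chromosome)
  loci$position <- as.integer(loci$position)
  if (nrow(loci) != n_loci)
    abort_validation("annotation has ", nrow(loci), " loci but matrices have ", n_loci)
  if (anyDuplicated(loci$locus_id))
    abort_validation("duplicated locus_id in annotation")
  if (any(is.na(loci$chromosome) | loci$chromosome == ""))
    abort_validation("empty chromosome label in annotation")

  for (nm in c("mothers", "fathers", "children")) {
    m <- get(nm)
    bad <- !(m %in% c(0L, 1L, 2L) | is.na(m))
    if (any(bad)) {
      idx <- which(bad)[1]
      abort_validation("invalid genotype code in ", nm, " at entry ", idx,
                       " (value ", m[idx], "); expected 0, 1, 2 or NA")
    }
  }
  storage.mode(mothers) <- storage.mode(fathers) <- storage.mode(children) <- "integer"

  if (is.null(family_ids)) family_ids <- paste0("fam", seq_len(n_fam))
  family_ids <- as.character(family_ids)
  if (length(family_ids) != n_fam)
    abort_validation("family_ids length does not match number of rows")

  dimnames(mothers) <- dimnames(fathers) <- dimnames(children) <-
    list(family_ids, loci$locus_id)

  viol <- !mendelian_consistent(mothers, fathers, children)
  viol[is.na(viol)] <- FALSE  # triples with missing members are not checkable
  n_masked <- sum(viol)
  if (n_masked > 0) {
    if (on_violation == "error")
      abort_validation(n_masked, " Mendelian-inconsistent genotype triple(s)")
    mothers[viol] <- NA_integer_
    fathers[viol] <- NA_integer_
    children[viol] <- NA_integer_
    warning(n_masked, " Mendelian-inconsistent triple(s) masked to missing",
            call. = FALSE)
  }

  structure(
    list(mothers = mothers, fathers = fathers, children = children,
         loci = loci, family_ids = family_ids),
    n_masked = n_masked,
    class = "triad_cohort"
  )
}

#' @export
print.triad_cohort <- function(x, ...) {
  cat("triad_cohort:", nrow(x$mothers), "families x", ncol(x$mothers), "loci on",
      length(unique(x$loci$chromosome)), "chromosome(s);",
      attr(x, "n_masked") %||% 0L, "masked triple(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of families / loci in a cohort
#' @param cohort A [triad_cohort()].
#' @return Integer count.
#' @export
n_families <- function(cohort) nrow(cohort$mothers)

#' @rdname n_families
#' @export
n_loci <- function(cohort) ncol(cohort$mothers)

# Vectorized Mendelian consistency for 0/1/2-coded triples. A homozygous-0
# parent can transmit only 0 alleles, homozygous-2 only 1; hence
# (m==2)+(f==2) <= c <= (m>0)+(f>0). NA where any member is missing.
mendelian_consistent <- function(m, f, c) {
  ((m == 2) + (f == 2) <= c) & (c <= (m > 0) + (f > 0))
}

#' Complement-sibling genotype from a triad
#'
#' The complement sibling is the hypothetical sibling built from the two
#' parental alleles NOT transmitted to the case; its genotype is
#' `mother + father - child` per locus. Inputs may be vectors or matrices.
#'
#' @param mother_g,father_g,child_g Genotypes in `{0, 1, 2}`,
#'   Mendelian-consistent.
#' @return The complement genotype(s), same shape as the inputs.
#' @export
#' @examples
#' compute_complement(2, 0, 1)  # 1: each parent's transmission is forced
#' compute_complement(1, 1, 2)  # 0: both designated alleles transmitted
compute_complement <- function(mother_g, father_g, child_g) {
  ok <- mendelian_consistent(mother_g, father_g, child_g)
  if (any(is.na(ok)))
    abort_validation("missing genotype in compute_complement; mask upstream instead")
  if (!all(ok))
    abort_validation("Mendelian-inconsistent triple(s) in compute_complement ",
                     "(e.g. index ", which(!ok)[1], "); data corruption?")
  mother_g + father_g - child_g
}

#' Read a triad cohort from genotype files
#'
#' Reads the three family-member genotype files plus a locus annotation TSV
#' and returns a validated [triad_cohort()]. Mendelian-inconsistent triples
#' are masked to missing with a warning (see [triad_cohort()]).
#'
#' Two genotype formats are supported. `"tsv"`: one tab-separated matrix per
#' family member, families as rows, loci as columns, a header row of locus
#' ids, first column `family_id`, missing as `NA`. `"plink-raw"`: an
#' additive-coded PLINK `.raw`-style export per family member (six leading
#' columns `FID IID PAT MAT SEX PHENOTYPE`, then one column per SNP, named
#' `<locus_id>_<allele>`); the family id is taken from `IID`.
#'
#' @param mother_file,father_file,child_file Paths to the genotype files.
#' @param annotation_file Path to a TSV with columns `locus_id`, `chromosome`,
#'   `position`.
#' @param format `"tsv"` or `"plink-raw"`.
#' @return A [triad_cohort()]; attribute `n_masked` counts masked triples.
#' @export
load_cohort <- function(mother_file, father_file, child_file, annotation_file,
                        format = c("tsv", "plink-raw")) {
  format <- match.arg(format)
  files <- c(mother = mother_file, father = father_file, child = child_file,
             annotation = annotation_file)
  for (i in seq_along(files))
    if (!file.exists(files[i]))
      abort_validation("file not found (", names(files)[i], "): ", files[i])

  ann <- as.data.frame(data.table::fread(annotation_file, sep = "\t"))
  reader <- if (format == "tsv") read_genotype_tsv else read_genotype_raw
  gm <- reader(mother_file)
  gf <- reader(father_file)
  gc <- reader(child_file)

  if (!identical(colnames(gm$geno), colnames(gf$geno)) ||
      !identical(colnames(gm$geno), colnames(gc$geno)))
    abort_validation("locus columns differ between the three genotype files")
  if (!identical(gm$family_id, gf$family_id) ||
      !identical(gm$family_id, gc$family_id))
    abort_validation("family ids differ between the three genotype files")
  if (!identical(colnames(gm$geno), ann$locus_id)) {
    if (!setequal(colnames(gm$geno), ann$locus_id))
      abort_validation("annotation locus_ids do not match genotype columns")
    ann <- ann[match(colnames(gm$geno), ann$locus_id), , drop = FALSE]
  }
  triad_cohort(gm$geno, gf$geno, gc$geno, ann, family_ids = gm$family_id)
}

read_genotype_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1))
  df <- as.data.frame(dt)
  fam <- as.character(df[[1]])
  geno <- df[, -1, drop = FALSE]
  check_genotype_codes(geno, path)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  list(geno = geno, family_id = fam)
}

read_genotype_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "-9"))
  df <- as.data.frame(dt)
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(lead %in% names(df)[1:6]))
    abort_validation("not a PLINK .raw-style file (missing leading columns): ", path)
  fam <- as.character(df[["IID"]])
  geno <- df[, -(1:6), drop = FALSE]
  # strip the _<counted allele> suffix PLINK appends to SNP column names
  names(geno) <- sub("_[A-Za-z0-9]+$", "", names(geno))
  check_genotype_codes(geno, path)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  list(geno = geno, family_id = fam)
}

check_genotype_codes <- function(geno, path) {
  for (j in seq_along(geno)) {
    v <- geno[[j]]
    bad <- which(!(is.na(v) | v %in% c(0, 1, 2)))
    if (length(bad))
      abort_validation("unknown genotype symbol in ", path, ", row ", bad[1],
                       ", column '", names(geno)[j], "': ", v[bad[1]])
  }
}

#' Write a triad cohort to TSV files
#'
#' Writes `mothers.tsv`, `fathers.tsv`, `children.tsv` (families as rows,
#' header of locus ids, first column `family_id`, missing as `NA`) plus
#' `loci.tsv` into `out_dir`. Output is bit-stable: writing the same cohort
#' twice gives identical bytes, and `load_cohort()` on the result restores
#' the cohort exactly.
#'
#' @param cohort A [triad_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "triad_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_validation("cannot create directory: ", out_dir)
  paths <- c(mothers = file.path(out_dir, "mothers.tsv"),
             fathers = file.path(out_dir, "fathers.tsv"),
             children = file.path(out_dir, "children.tsv"),
             loci = file.path(out_dir, "loci.tsv"))
  for (nm in c("mothers", "fathers", "children")) {
    m <- cohort[[nm]]
    df <- data.frame(family_id = cohort$family_ids, m,
                     check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(df, paths[nm], sep = "\t", na = "NA", quote = FALSE)
  }
  data.table::fwrite(cohort$loci, paths["loci"], sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(paths)
}

#' Construct a SNP-set
#'
#' A SNP-set is an unordered collection of distinct candidate SNPs, each a
#' (locus, origin) pair where origin is `"child"` (scored case vs complement
#' sibling) or `"maternal"` (scored mother vs father). The same locus may
#' appear twice, once per origin, so same-locus maternal-fetal
#' incompatibilities are expressible.
#'
#' @param locus_index Integer indices into the cohort's locus table.
#' @param origin Character vector, each `"child"` or `"maternal"`, recycled
#'   if length one.
#' @return A data frame of class `snp_set` with columns `locus_index`,
#'   `origin`, in canonical (locus, origin) order.
#' @export
snp_set <- function(locus_index, origin) {
  locus_index <- as.integer(locus_index)
  if (length(origin) == 1) origin <- rep(origin, length(locus_index))
  if (!all(origin %in% c("child", "maternal")))
    abort_validation("origin must be 'child' or 'maternal'")
  if (length(locus_index) < 1) abort_validation("empty SNP-set")
  df <- data.frame(locus_index = locus_index, origin = as.character(origin),
                   stringsAsFactors = FALSE)
  df <- df[order(df$locus_index, df$origin), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df)) abort_validation("duplicate (locus, origin) in SNP-set")
  class(df) <- c("snp_set", "data.frame")
  df
}

as_snp_set <- function(x) {
  if (inherits(x, "snp_set")) return(x)
  snp_set(x$locus_index, x$origin)
}

# Canonical string key of a SNP-set (used for dedup / tie-breaks).
snp_set_key <- function(set) {
  set <- as_snp_set(set)
  paste(paste0(set$locus_index, ":", ifelse(set$origin == "maternal", "m", "c")),
        collapse = ",")
}

#' Read / write a candidate-SNP list
#'
#' A candidate list designates each candidate as a maternal or child SNP.
#' On disk it is a TSV with columns `locus_id` and `origin`
#' (`child`/`maternal`); in memory it is a data frame with columns
#' `locus_index`, `origin`, `locus_id`.
#'
#' @param path TSV file path.
#' @param cohort A [triad_cohort()] used to resolve `locus_id` to indices.
#' @return `read_candidate_list()`: the candidate data frame.
#' @export
read_candidate_list <- function(path, cohort) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("locus_id", "origin") %in% names(df)))
    abort_validation("candidate list needs columns locus_id, origin")
  idx <- match(as.character(df$locus_id), cohort$loci$locus_id)
  if (anyNA(idx))
    abort_validation("unknown locus_id in candidate list: ",
                     df$locus_id[which(is.na(idx))[1]])
  make_candidates(cohort, idx, as.character(df$origin))
}

#' @rdname read_candidate_list
#' @param candidates Candidate data frame as returned by
#'   [read_candidate_list()] or [make_candidates()].
#' @return `write_candidate_list()`: the path, invisibly.
#' @export
write_candidate_list <- function(candidates, path) {
  data.table::fwrite(candidates[, c("locus_id", "origin")], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Build a candidate data frame from indices and origins
#'
#' @param cohort A [triad_cohort()].
#' @param locus_index Integer locus indices.
#' @param origin `"child"`/`"maternal"` per candidate.
#' @return Data frame with columns `locus_index`, `origin`, `locus_id`;
#'   (locus, origin) pairs must be unique.
#' @export
make_candidates <- function(cohort, locus_index, origin) {
  locus_index <- as.integer(locus_index)
  if (any(locus_index < 1 | locus_index > n_loci(cohort)))
    abort_validation("locus_index out of range")
  if (!all(origin %in% c("child", "maternal")))
    abort_validation("origin must be 'child' or 'maternal'")
  df <- data.frame(locus_index = locus_index, origin = origin,
                   locus_id = cohort$loci$locus_id[locus_index],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("locus_index", "origin")]))
    abort_validation("duplicate (locus, origin) pair in candidate list")
  rownames(df) <- NULL
  df
}
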