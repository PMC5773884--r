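#' Specify a twin/sibling family structure
#'
#' Defines the composition of a cohort as counts of family configurations:
#' monozygotic (MZ) and dizygotic (DZ) twin pairs, sibling pairs, trios
#' (a twin pair plus one non-twin sibling, or three siblings), and
#' singletons. Families never exceed three members, the classical extended
#' twin design that adds power over pairs alone.
#'
#' @param n_mz_pairs,n_dz_pairs,n_sib_pairs number of complete MZ, DZ and
#'   non-twin sibling pairs. Sibling pairs are treated as DZ (expected
#'   additive relatedness 0.5).
#' @param n_mz_trios,n_dz_trios number of trios consisting of an MZ (resp.
#'   DZ) twin pair plus one sibling.
#' @param n_sib_trios number of trios of three non-twin siblings.
#' @param n_singletons number of individuals with no relatives in the sample.
#' @return an object of class `family_structure_spec` (a named list of
#'   counts with an `n_individuals` field).
#' @seealso [build_family_structure()], [discovery_family_structure()]
#' @export
family_structure_spec <- function(n_mz_pairs = 0L, n_dz_pairs = 0L,
                                  n_sib_pairs = 0L, n_mz_trios = 0L,
                                  n_dz_trios = 0L, n_sib_trios = 0L,
                                  n_singletons = 0L) {
  counts <- c(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              n_sib_pairs = n_sib_pairs, n_mz_trios = n_mz_trios,
              n_dz_trios = n_dz_trios, n_sib_trios = n_sib_trios,
              n_singletons = n_singletons)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("all family counts must be non-negative integers")
  counts <- stats::setNames(as.integer(counts), names(counts))
  spec <- as.list(counts)
  spec$n_individuals <- 2L * (counts[["n_mz_pairs"]] + counts[["n_dz_pairs"]] +
                              counts[["n_sib_pairs"]]) +
    3L * (counts[["n_mz_trios"]] + counts[["n_dz_trios"]] +
          counts[["n_sib_trios"]]) +
    counts[["n_singletons"]]
  structure(spec, class = "family_structure_spec")
}

#' Family structure of the discovery twin sample
#'
#' Convenience constructor for the discovery-cohort composition used
#' throughout the examples and power calculations: 101 MZ pairs, 142 DZ
#' pairs, 32 sibling pairs, 9 MZ trios, 14 DZ trios and 214 singletons
#' (833 individuals in total).
#'
#' @return a [family_structure_spec()].
#' @export
discovery_family_structure <- function() {
  family_structure_spec(n_mz_pairs = 101L, n_dz_pairs = 142L,
                        n_sib_pairs = 32L, n_mz_trios = 9L,
                        n_dz_trios = 14L, n_singletons = 214L)
}

#' @export
print.family_structure_spec <- function(x, ...) {
  cat("Family structure:", x$n_individuals, "individuals\n")
  cat(sprintf("  pairs:  %d MZ, %d DZ, %d sibling\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_sib_pairs))
  cat(sprintf("  trios:  %d MZ+sib, %d DZ+sib, %d sibling\n",
              x$n_mz_trios, x$n_dz_trios, x$n_sib_trios))
  cat(sprintf("  singletons: %d\n", x$n_singletons))
  invisible(x)
}

#' Build the individual table for a family structure
#'
#' Expands a [family_structure_spec()] into one row per individual with
#' deterministic identifiers, a family id, and a relationship code.
#' Relationship codes are `MZ` (member of an MZ twin pair), `DZ` (member of
#' a DZ twin pair), `SIB` (non-twin sibling, including the third member of a
#' twin trio) and `SINGLETON`. DZ twins and ordinary siblings carry the same
#' expected additive relatedness (0.5), so the distinction only matters for
#' identifying which two members form the MZ pair of a family.
#'
#' @param spec a [family_structure_spec()].
#' @return a `family_set`: a data frame with columns `individual_id`,
#'   `family_id`, `rel` and `family_type`.
#' @export
build_family_structure <- function(spec) {
  if (!inherits(spec, "family_structure_spec"))
    spec <- do.call(family_structure_spec, as.list(spec))
  configs <- list(
    mz_pair  = list(n = spec$n_mz_pairs,  rel = c("MZ", "MZ")),
    dz_pair  = list(n = spec$n_dz_pairs,  rel = c("DZ", "DZ")),
    sib_pair = list(n = spec$n_sib_pairs, rel = c("SIB", "SIB")),
    mz_trio  = list(n = spec$n_mz_trios,  rel = c("MZ", "MZ", "SIB")),
    dz_trio  = list(n = spec$n_dz_trios,  rel = c("DZ", "DZ", "SIB")),
    sib_trio = list(n = spec$n_sib_trios, rel = c("SIB", "SIB", "SIB")),
    singleton = list(n = spec$n_singletons, rel = "SINGLETON"))
  fam_type <- character(0); rel <- character(0); fam_rep <- integer(0)
  member <- integer(0)
  fid <- 0L
  fam_id <- integer(0)
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    if (cfg$n == 0L) next
    m <- length(cfg$rel)
    fam_id <- c(fam_id, rep(fid + seq_len(cfg$n), each = m))
    fid <- fid + cfg$n
    fam_type <- c(fam_type, rep(nm, cfg$n * m))
    rel <- c(rel, rep(cfg$rel, cfg$n))
    member <- c(member, rep(seq_len(m), cfg$n))
  }
  n <- length(rel)
  fams <- data.frame(
    individual_id = sprintf("I%04d", seq_len(max(n, 1L))[seq_len(n)]),
    family_id = sprintf("F%04d", fam_id),
    rel = rel,
    family_type = fam_type,
    member = member,
    stringsAsFactors = FALSE)
  if (n == 0L)
    fams <- fams[0, , drop = FALSE]
  attr(fams, "spec") <- spec
  class(fams) <- c("family_set", "data.frame")
  fams
}

#' Split a family set into per-family member indices
#'
#' @param fams a `family_set` data frame.
#' @return named list of integer row-index vectors, one per family.
#' @keywords internal
family_indices <- function(fams) {
  split(seq_len(nrow(fams)), fams$family_id)
}

#' Expected additive-relatedness matrix of one family
#'
#' Entries are 1 on the diagonal and for MZ co-twins, 0.5 for any other pair
#' of family members (DZ twins and full siblings), and would be 0 across
#' families (never the case within one family here).
#'
#' @param rel character vector of relationship codes for the family members.
#' @return an m x m relatedness matrix.
#' @export
relatedness_matrix <- function(rel) {
  m <- length(rel)
  R <- matrix(0.5, m, m)
  diag(R) <- 1
  mz <- which(rel == "MZ")
  if (length(mz) > 2L)
    stop("a family may contain at most one MZ pair")
  if (length(mz) == 2L) R[mz[1], mz[2]] <- R[mz[2], mz[1]] <- 1
  if (length(mz) == 1L && m > 1L)
    stop("inconsistent relationship codes: lone MZ member in a family of ", m)
  R
}
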