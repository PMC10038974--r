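#' @title CYP2D6 star-allele and diplotype handling
#' @name genotypes
#' @description
#' Translation of CYP2D6 diplotypes (pairs of star alleles, possibly carrying
#' a gene-duplication suffix) into genotype groups and genotype-predicted
#' metabolizer phenotypes. The panel covers the eight alleles routinely
#' genotyped in many TDM laboratories: the lack-of-function ("defective")
#' alleles *3, *4, *5 and *6, the reduced-function alleles *9, *10 and *41,
#' and the fully functional wild-type *1.
#'
#' The phenotype translation follows the DPWG/CPIC consensus grouping used by
#' many clinical laboratories:
#' \itemize{
#'   \item PM: two defective alleles (Def/def)
#'   \item IM: Def/red, Red/red, or *1/def
#'   \item NM: *1/red or *1/*1 (note: *1/red as NM predates the current CPIC
#'     activity-score boundary, which places *1/*41 in IM; this package keeps
#'     the laboratory grouping with *1/red in NM)
#'   \item UM: *1/*1 with a duplication (*1/*1xN)
#'   \item inconclusive: any duplication combined with a reduced- and/or
#'     non-functional allele, because copy-number assays typically cannot
#'     determine which allele is duplicated
#' }
NULL

.allele_classes <- c(
  "*1"  = "functional",
  "*3"  = "defective",
  "*4"  = "defective",
  "*5"  = "defective",
  "*6"  = "defective",
  "*9"  = "reduced",
  "*10" = "reduced",
  "*41" = "reduced"
)

#' Genotype-group and phenotype factor levels
#'
#' @return Character vector of the ten genotype-group labels
#'   (`genotype_groups()`) or the five phenotype labels (`phenotypes()`), in
#'   canonical display order. The first seven genotype groups are conclusive;
#'   the three "xN" groups denote inconclusive duplication genotypes.
#' @export
genotype_groups <- function() {
  c("*1/*1xN", "*1/*1", "*1/red", "*1/def", "Red/red", "Def/red", "Def/def",
    "*1/red xN", "*1/def xN", "Red/def xN")
}

#' @rdname genotype_groups
#' @export
phenotypes <- function() {
  c("UM", "NM", "IM", "PM", "inconclusive")
}

#' Genotype groups that enter the ROC and regression analyses
#'
#' @return The seven conclusive genotype-group labels (no duplication
#'   ambiguity).
#' @export
conclusive_groups <- function() genotype_groups()[1:7]

#' Parse a star-allele string
#'
#' Accepts the laboratory export dialect `"*4"`, `"*1xN"`, `"*1 x2"` etc.
#' A duplication suffix `xN` with unspecified N is recorded as copy number 2
#' (the minimal duplication).
#'
#' @param x Character vector of allele strings.
#' @return A data.frame with columns `star_name`, `functional_class`
#'   (`"functional"`, `"reduced"` or `"defective"`) and `copy_number`
#'   (integer, >= 1).
#' @export
#' @examples
#' parse_allele(c("*4", "*41", "*1xN"))
parse_allele <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^\\s*(\\*\\d+)\\s*(?:[xX]\\s*([0-9]+|N))?\\s*$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unrecognised CYP2D6 allele string: ",
         paste(sQuote(x[bad]), collapse = ", "))
  }
  star <- vapply(m, `[`, "", 2L)
  copy <- vapply(m, `[`, "", 3L)
  unknown <- !(star %in% names(.allele_classes))
  if (any(unknown)) {
    stop("CYP2D6 allele(s) outside the supported panel: ",
         paste(sQuote(unique(star[unknown])), collapse = ", "),
         " (supported: ", paste(names(.allele_classes), collapse = ", "), ")")
  }
  cn <- ifelse(copy == "", 1L, ifelse(copy == "N", 2L, suppressWarnings(as.integer(copy))))
  if (any(!is.na(cn) & cn < 1L)) stop("copy number must be >= 1")
  data.frame(
    star_name = star,
    functional_class = unname(.allele_classes[star]),
    copy_number = as.integer(cn),
    stringsAsFactors = FALSE
  )
}

#' Functional class of a star allele
#'
#' @param star_name Character vector of allele strings (duplication suffixes
#'   allowed and ignored for the class).
#' @return Character vector: `"functional"`, `"reduced"` or `"defective"`.
#' @export
#' @examples
#' classify_allele("*4")   # "defective"
#' classify_allele("*41")  # "reduced"
classify_allele <- function(star_name) {
  parse_allele(star_name)$functional_class
}

.group_phenotype <- c(
  "*1/*1xN"    = "UM",
  "*1/*1"      = "NM",
  "*1/red"     = "NM",
  "*1/def"     = "IM",
  "Red/red"    = "IM",
  "Def/red"    = "IM",
  "Def/def"    = "PM",
  "*1/red xN"  = "inconclusive",
  "*1/def xN"  = "inconclusive",
  "Red/def xN" = "inconclusive"
)

.pair_group <- function(class_a, class_b, duplicated) {
  cls <- sort(c(class_a, class_b)) # "defective" < "functional" < "reduced"
  key <- paste(cls, collapse = "+")
  base <- switch(key,
    "functional+functional" = "*1/*1",
    "functional+reduced"    = "*1/red",
    "defective+functional"  = "*1/def",
    "reduced+reduced"       = "Red/red",
    "defective+reduced"     = "Def/red",
    "defective+defective"   = "Def/def",
    stop("unreachable allele class pair: ", key)
  )
  if (!duplicated) return(base)
  # Any duplication: *1/*1 becomes the UM group; anything carrying a reduced
  # or defective allele cannot be resolved by the copy-number assay.
  switch(base,
    "*1/*1"  = "*1/*1xN",
    "*1/red" = "*1/red xN",
    "*1/def" = "*1/def xN",
    "Red/def xN" # Red/red, Def/red, Def/def with duplication: pooled group
  )
}

#' Translate diplotypes to genotype groups and phenotypes
#'
#' @param diplotype Character vector of diplotype strings such as `"*1/*4"` or
#'   `"*1xN/*41"`; whitespace around alleles is tolerated. The result is
#'   independent of allele order.
#' @return A data.frame with columns `cyp2d6_diplotype`, `genotype_group`
#'   (factor with levels [genotype_groups()]) and `phenotype` (factor with
#'   levels [phenotypes()]).
#' @export
#' @examples
#' phenotype_of(c("*4/*5", "*1/*41", "*1xN/*41"))
phenotype_of <- function(diplotype) {
  diplotype <- as.character(diplotype)
  parts <- strsplit(diplotype, "/", fixed = TRUE)
  nbad <- vapply(parts, length, 1L) != 2L
  if (any(nbad)) {
    stop("diplotype must contain exactly two alleles separated by '/': ",
         paste(sQuote(diplotype[nbad]), collapse = ", "))
  }
  a <- parse_allele(vapply(parts, `[`, "", 1L))
  b <- parse_allele(vapply(parts, `[`, "", 2L))
  dup <- a$copy_number > 1L | b$copy_number > 1L
  grp <- mapply(.pair_group, a$functional_class, b$functional_class, dup)
  data.frame(
    cyp2d6_diplotype = diplotype,
    genotype_group = factor(grp, levels = genotype_groups()),
    phenotype = factor(unname(.group_phenotype[grp]), levels = phenotypes()),
    stringsAsFactors = FALSE
  )
}

#' Append genotype-group and phenotype columns to a patient table
#'
#' @param records A data.frame with a `cyp2d6_diplotype` column.
#' @return `records` with `genotype_group` and `phenotype` columns added
#'   (replaced if already present).
#' @export
call_phenotypes <- function(records) {
  stopifnot(is.data.frame(records), "cyp2d6_diplotype" %in% names(records))
  ph <- phenotype_of(records$cyp2d6_diplotype)
  records$genotype_group <- ph$genotype_group
  records$phenotype <- ph$phenotype
  records
}
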