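# Sex-marker panel statistics: marker classification over a sexed PCR
# panel, the panel's false-positive probability, Mendelian sex-ratio
# expectations under a ZW system, and biplex band-pattern sex calls.

#' Classify a presence/absence marker over a sexed panel
#'
#' A marker is `sex_specific` when present in every female and absent from
#' every male; `near_specific` when exactly one animal is discordant with
#' that ideal pattern (one male carrier, or one female non-carrier);
#' `non_specific` when present in every animal; `failed` when absent from
#' every animal; otherwise `polymorphic` (partial presence with no clean
#' sex trend — e.g. present in four of six females and no males).
#'
#' @param presence logical vector: marker presence per animal.
#' @param sexes character vector (`"female"`/`"male"`), same length; the
#'   panel must contain at least one of each sex.
#' @return one of `"sex_specific"`, `"near_specific"`, `"polymorphic"`,
#'   `"non_specific"`, `"failed"`.
#' @export
classify_panel <- function(presence, sexes) {
  stopifnot(length(presence) == length(sexes), is.logical(presence))
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  if (!any(sexes == "female") || !any(sexes == "male"))
    stop("panel must contain both sexes")
  if (!any(presence)) return("failed")
  if (all(presence)) return("non_specific")
  discordant <- sum(presence != (sexes == "female"))
  if (discordant == 0) return("sex_specific")
  if (discordant == 1) return("near_specific")
  "polymorphic"
}

#' False-positive probability of a sexed validation panel
#'
#' Probability that a marker with no sex linkage — present in each animal
#' independently with probability `p` (1/2 for a dominant marker
#' segregating at intermediate frequency) — shows the perfect
#' female-present / male-absent pattern by chance:
#' `p^n_f * (1 - p)^n_m`. For a panel of six females and six males at
#' `p = 1/2` this is `2^-12`, about 2e-4.
#'
#' @param n_f,n_m numbers of females and males in the panel.
#' @param p per-animal presence probability under the sex-independent null.
#' @return the false-positive probability.
#' @export
panel_fpr <- function(n_f, n_m, p = 1 / 2) {
  stopifnot(n_f >= 0, n_m >= 0, p > 0, p < 1)
  p^n_f * (1 - p)^n_m
}

#' Build a ZW-system cross model
#'
#' @param p1,p2 parental sex-chromosome genotypes, each a string of two
#'   chromosomes among `"ZZ"`, `"ZW"`, `"WW"`.
#' @param viability named logical vector over offspring genotypes
#'   (`ZZ`, `ZW`, `WW`); genotypes omitted default to viable.
#' @return a `cross_model` list: `p1`, `p2`, `viability`, and the sex rule
#'   (ZZ is male; ZW and WW are female).
#' @export
cross_model <- function(p1, p2, viability = c(ZZ = TRUE, ZW = TRUE,
                                              WW = TRUE)) {
  parse <- function(g) {
    ch <- strsplit(toupper(g), "")[[1]]
    if (length(ch) != 2 || !all(ch %in% c("Z", "W")))
      stop("genotype must be two chromosomes among Z and W, got ", g)
    ch
  }
  v <- c(ZZ = TRUE, ZW = TRUE, WW = TRUE)
  v[names(viability)] <- viability
  structure(list(p1 = parse(p1), p2 = parse(p2), viability = v,
                 sex_rule = c(ZZ = "male", ZW = "female", WW = "female")),
            class = "cross_model")
}

#' Expected offspring sex ratio for a ZW-system cross
#'
#' Enumerates the four equiprobable gamete combinations, drops inviable
#' genotypes, renormalises, and applies the sex rule (ZZ male, ZW and WW
#' female). A ZW x ZW cross with WW viable yields 3:1 female:male; a
#' ZZ x WW cross yields all females.
#'
#' @param cross a `cross_model`.
#' @return list with `p_female`, `p_male` (summing to 1 over viable
#'   offspring), `ratio` (female:male; `Inf` when no male offspring), and
#'   `genotype_probs`.
#' @export
expected_sex_ratio <- function(cross) {
  stopifnot(inherits(cross, "cross_model"))
  combos <- expand.grid(g1 = cross$p1, g2 = cross$p2,
                        stringsAsFactors = FALSE)
  # canonical order: Z before W (ZZ / ZW / WW)
  geno <- apply(combos, 1, function(r)
    paste(sort(r, decreasing = TRUE), collapse = ""))
  tab <- table(geno) / length(geno)
  viable <- tab[cross$viability[names(tab)]]
  if (length(viable) == 0 || sum(viable) == 0)
    stop("no viable offspring genotype in this cross")
  probs <- viable / sum(viable)
  sex <- cross$sex_rule[names(probs)]
  p_f <- sum(probs[sex == "female"])
  p_m <- sum(probs[sex == "male"])
  list(p_female = unname(p_f), p_male = unname(p_m),
       ratio = unname(if (p_m == 0) Inf else p_f / p_m),
       genotype_probs = stats::setNames(as.numeric(probs), names(probs)))
}

#' Sex call from a biplex PCR band pattern
#'
#' The assay combines a female-specific amplicon (219 bp) with an internal
#' control amplicon (486 bp) present in both sexes. Two bands call a
#' female; the control band alone calls a male; a missing control band
#' voids the reaction regardless of other bands.
#'
#' @param bands numeric vector of observed product sizes in bp.
#' @param female_size,control_size expected amplicon sizes.
#' @param tol band-matching tolerance in bp (gel resolution).
#' @return `"female"`, `"male"`, or `"fail"`.
#' @export
biplex_call <- function(bands, female_size = 219, control_size = 486,
                        tol = 10) {
  has <- function(size) any(abs(bands - size) <= tol)
  if (length(bands) == 0 || !has(control_size)) return("fail")
  if (has(female_size)) "female" else "male"
}
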