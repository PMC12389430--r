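# Non-spatial structure: species composition, diversity, importance
# values, diameter-class distribution.

#' Species abundance profile of a stand
#'
#' @param stand a [ForestStand-class].
#' @return data.frame with one row per species: `species`, `n`
#'   (individuals), `basal` (summed basal area at breast height, cm^2,
#'   pi * (DBH/2)^2), `p` (proportion of individuals).
#' @export
abundanceProfile <- function(stand) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  if (nrow(tr) == 0) stop("empty stand")
  n <- tapply(tr$species, tr$species, length)
  basal <- tapply(pi * (tr$dbh / 2)^2, tr$species, sum)
  out <- data.frame(species = names(n), n = as.integer(n),
                    basal = as.numeric(basal), stringsAsFactors = FALSE)
  out$p <- out$n / sum(out$n)
  rownames(out) <- NULL
  out[order(-out$n, out$species), ]
}

#' Patrick richness (species count)
#'
#' @param x a [ForestStand-class], an abundance profile, or a vector of
#'   species counts.
#' @return R = S, the number of species present.
#' @export
patrickRichness <- function(x) {
  counts <- .speciesCounts(x)
  sum(counts > 0)
}

#' Margalef richness index
#'
#' MA = (S - 1) / ln N.
#'
#' @param S number of species.
#' @param N total number of individuals (>= 2).
#' @return the Margalef index.
#' @examples
#' round(margalefIndex(10, 52), 2)   # 2.28
#' round(margalefIndex(28, 166), 2)  # 5.28
#' @export
margalefIndex <- function(S, N) {
  if (N < 2) stop("N must be >= 2")
  if (S < 1) stop("S must be >= 1")
  (S - 1) / log(N)
}

#' Shannon-Wiener diversity index
#'
#' H = -sum pi ln pi (natural logarithm; empty species contribute 0).
#'
#' @param x a [ForestStand-class], an abundance profile, or species counts.
#' @return H >= 0; H = ln S for uniform abundances.
#' @export
shannonIndex <- function(x) {
  counts <- .speciesCounts(x)
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Simpson diversity index
#'
#' D = 1 - sum pi^2.
#'
#' @param x a [ForestStand-class], an abundance profile, or species counts.
#' @return D in [0, 1); 0 for a monoculture.
#' @export
simpsonIndex <- function(x) {
  counts <- .speciesCounts(x)
  as.numeric(vegan::diversity(counts, index = "simpson"))
}

#' Pielou evenness
#'
#' E = H / ln S; undefined for a single species (returns NaN with a
#' warning).
#'
#' @param H Shannon-Wiener index.
#' @param S number of species.
#' @return E in \[0, 1\].
#' @examples
#' pielouEvenness(1.65, 10)  # 0.717, above the 0.71 bound typical of
#'                           # well-mixed natural stands
#' @export
pielouEvenness <- function(H, S) {
  if (S < 1) stop("S must be >= 1")
  if (S == 1) {
    warning("Pielou evenness is undefined for a single species")
    return(NaN)
  }
  H / log(S)
}

.speciesCounts <- function(x) {
  if (is(x, "ForestStand")) x <- abundanceProfile(x)
  if (is.data.frame(x)) {
    counts <- stats::setNames(x$n, x$species)
  } else counts <- x
  if (any(counts < 0) || sum(counts) == 0) stop("invalid species counts")
  counts
}

#' Plot-level diversity summary
#'
#' @param stand a [ForestStand-class].
#' @return one-row data.frame: `N`, `S` (= Patrick R), `margalef`,
#'   `shannon`, `simpson`, `pielou`.
#' @export
diversitySummary <- function(stand) {
  prof <- abundanceProfile(stand)
  S <- nrow(prof); N <- sum(prof$n)
  H <- shannonIndex(prof)
  data.frame(N = N, S = S,
             margalef = margalefIndex(S, N),
             shannon = H,
             simpson = simpsonIndex(prof),
             pielou = if (S > 1) pielouEvenness(H, S) else NaN)
}

#' Relative abundance, frequency and dominance per species
#'
#' RA is a species' percentage of all individuals; RD its percentage of the
#' stand's total basal area at breast height; RF its occupied-quadrat count
#' as a percentage of the summed occupied-quadrat counts of all species,
#' using a square quadrat grid (default 5 m, i.e. 25 quadrats in a 25 m
#' plot) as the within-plot sampling unit.
#'
#' @param stand a [ForestStand-class].
#' @param quadratSize quadrat side (m).
#' @return data.frame: `species`, `n`, `RA`, `RF`, `RD` (percent; each
#'   column sums to 100 within the plot).
#' @export
importanceValueComponents <- function(stand, quadratSize = 5) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  if (nrow(tr) == 0) stop("empty stand")
  L <- plotSize(stand)
  nq <- max(1L, floor(L / quadratSize))
  qx <- pmin(floor(tr$x / quadratSize), nq - 1L)
  qy <- pmin(floor(tr$y / quadratSize), nq - 1L)
  quad <- qx * nq + qy
  basal <- pi * (tr$dbh / 2)^2
  sp <- sort(unique(tr$species))
  n <- vapply(sp, function(s) sum(tr$species == s), numeric(1))
  ba <- vapply(sp, function(s) sum(basal[tr$species == s]), numeric(1))
  fr <- vapply(sp, function(s) length(unique(quad[tr$species == s])),
               numeric(1))
  if (sum(ba) <= 0) stop("zero total basal area")
  out <- data.frame(species = sp, n = as.integer(n),
                    RA = 100 * n / sum(n),
                    RF = 100 * fr / sum(fr),
                    RD = 100 * ba / sum(ba),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Importance value from its three components
#'
#' IV = (RA + RF + RD) / 3, all in percent.
#'
#' @param RA,RF,RD relative abundance, frequency and dominance (percent,
#'   each in \[0, 100\]).
#' @return IV in percent.
#' @examples
#' round(importanceValue(39.13, 31.58, 40.30), 2)  # 37.00
#' @export
importanceValue <- function(RA, RF, RD) {
  v <- c(RA, RF, RD)
  if (any(v < 0 | v > 100)) stop("components must lie in [0, 100]")
  (RA + RF + RD) / 3
}

#' Importance-value table of a stand
#'
#' @param stand a [ForestStand-class].
#' @param quadratSize quadrat side (m) for the frequency component.
#' @return data.frame sorted by decreasing IV: `species`, `n`, `RA`, `RF`,
#'   `RD`, `IV` (percent).
#' @export
importanceValueTable <- function(stand, quadratSize = 5) {
  comp <- importanceValueComponents(stand, quadratSize)
  comp$IV <- (comp$RA + comp$RF + comp$RD) / 3
  comp[order(-comp$IV, comp$species), ]
}

#' Diameter-class distribution
#'
#' Half-open 10 cm bins anchored at the 5 cm census minimum: class I is
#' [5, 15) cm, class II [15, 25) cm, and so on. Also diagnoses the
#' inverse-J shape (non-increasing counts from class I upward), the
#' signature of active regeneration.
#'
#' @param x a [ForestStand-class] or a numeric vector of DBH (cm).
#' @param width class width (cm).
#' @param origin lower edge of class I (cm); DBH below it is an error.
#' @return list: `counts` (named by Roman class labels), `breaks`,
#'   `inverseJ` (logical).
#' @export
diameterClasses <- function(x, width = 10, origin = 5) {
  dbh <- if (is(x, "ForestStand")) treeData(x)$dbh else x
  if (length(dbh) == 0) stop("no DBH values")
  cls <- .dbhClassIndex(dbh, width, origin)
  ncls <- max(cls)
  counts <- stats::setNames(tabulate(cls, ncls), .romanLabels(ncls))
  list(counts = counts,
       breaks = origin + width * (0:ncls),
       inverseJ = all(diff(counts) <= 0))
}

#' Taxonomic composition summary
#'
#' Counts distinct families, genera and species given a taxonomy lookup.
#' Species absent from the taxonomy are counted as their own genus and
#' family, with a warning.
#'
#' @param stand a [ForestStand-class].
#' @param taxonomy data.frame with columns `species`, `genus`, `family`
#'   (may be empty).
#' @return named integer vector: `families`, `genera`, `species`.
#' @export
compositionSummary <- function(stand, taxonomy = NULL) {
  stopifnot(is(stand, "ForestStand"))
  sp <- unique(treeData(stand)$species)
  if (is.null(taxonomy) || nrow(taxonomy) == 0) {
    warning("no taxonomy provided; genus and family counts equal species")
    return(c(families = length(sp), genera = length(sp),
             species = length(sp)))
  }
  m <- match(sp, taxonomy$species)
  if (any(is.na(m)))
    warning(sprintf("%d species missing from the taxonomy; counted as %s",
                    sum(is.na(m)), "their own genus and family"))
  genus <- ifelse(is.na(m), paste0("unknown:", sp), taxonomy$genus[m])
  family <- ifelse(is.na(m), paste0("unknown:", sp), taxonomy$family[m])
  c(families = length(unique(family)), genera = length(unique(genus)),
    species = length(sp))
}
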