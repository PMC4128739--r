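# Use-versus-availability habitat selection and functional reclassification.

#' Habitat availability within a home range
#'
#' Fraction of landscape cells of each cover type whose centres fall inside
#' the home-range mask.
#'
#' @param landscape a \linkS4class{GridLandscape} (structural or functional)
#' @param hr a \linkS4class{HomeRange}
#' @return named numeric vector of availability proportions over all legend
#'   codes (zeros included), summing to 1
#' @export
availabilityWithinRange <- function(landscape, hr) {
  stopifnot(is(landscape, "GridLandscape"), is(hr, "HomeRange"))
  g <- classGrid(landscape)
  nr <- nrow(g); nc <- ncol(g)
  centers <- cellCenters(seq_len(nr * nc), nr, cellSize(landscape),
                         gridOrigin(landscape))
  mask <- hrMask(hr)
  idx <- cellAt(centers, nrow(mask), ncol(mask), cellSize(hr), gridOrigin(hr))
  inside <- !is.na(idx) & mask[ifelse(is.na(idx), 1L, idx)]
  if (!any(inside))
    stop("home range does not overlap the landscape")
  legend <- habitatLegend(landscape)
  tab <- table(factor(as.vector(g)[inside], levels = names(legend)))
  setNames(as.numeric(tab) / sum(tab), unname(legend))
}

# Agresti-Coull interval for a binomial proportion at confidence level conf
agrestiCoull <- function(x, n, conf) {
  z <- qnorm(1 - (1 - conf) / 2)
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  c(low = max(0, pt - hw), high = min(1, pt + hw))
}

#' Test habitat selection against availability
#'
#' Compares the observed distribution of an individual's locations over cover
#' types with the distribution expected under random habitat choice: a
#' Pearson goodness-of-fit chi-square over the cover types available in the
#' home range, plus per-type simultaneous confidence intervals for the used
#' proportion (Agresti-Coull, Bonferroni-adjusted across the k tested types).
#' A cover type is called \emph{selected} when its availability falls below
#' the lower confidence limit of its used proportion, \emph{avoided} when
#' availability exceeds the upper limit, and \emph{neutral} otherwise. Types
#' that are unavailable (availability 0) but used are called selected and
#' excluded from the chi-square.
#'
#' @param used_counts named integer vector of location counts per cover type
#' @param avail_prop named availability proportions (must sum to 1)
#' @param conf family confidence level (default 0.95)
#' @param behavior behaviour context stored in the result
#' @param individual individual identifier stored in the result
#' @return a \linkS4class{SelectionTable}
#' @examples
#' selectionTest(c(road = 31, other = 69), c(road = 0.01, other = 0.99),
#'               behavior = "foraging", individual = "933")
#' @export
selectionTest <- function(used_counts, avail_prop, conf = 0.95,
                          behavior = "foraging", individual = "unknown") {
  stopifnot(sum(used_counts) >= 1)
  if (abs(sum(avail_prop) - 1) > 1e-6)
    stop("avail_prop must sum to 1")
  extra <- setdiff(names(used_counts)[used_counts > 0], names(avail_prop))
  if (length(extra))
    stop("used counts in categories absent from availability: ",
         paste(extra, collapse = ", "))
  types <- union(names(avail_prop), names(used_counts))
  used <- setNames(rep(0, length(types)), types)
  used[names(used_counts)] <- used_counts
  avail <- setNames(rep(0, length(types)), types)
  avail[names(avail_prop)] <- avail_prop
  # drop types absent from both use and availability
  keep <- !(avail == 0 & used == 0)
  types <- types[keep]; used <- used[keep]; avail <- avail[keep]
  n <- sum(used)
  used_prop <- used / n

  tested <- avail > 0
  k <- sum(tested)
  level <- 1 - (1 - conf) / k
  ci <- t(vapply(used, function(x) agrestiCoull(x, n, level), numeric(2)))
  call <- ifelse(avail < ci[, "low"], "selected",
                 ifelse(avail > ci[, "high"], "avoided", "neutral"))
  call[!tested & used > 0] <- "selected"  # used despite zero availability

  chi <- sum((used[tested] - sum(used[tested]) * avail[tested])^2 /
             (sum(used[tested]) * avail[tested]))
  df <- as.integer(k - 1L)
  p <- pchisq(chi, df, lower.tail = FALSE)
  new("SelectionTable",
      table = data.frame(cover_type = types, used_count = as.numeric(used),
                         used_prop = as.numeric(used_prop),
                         avail_prop = as.numeric(avail),
                         ci_low = ci[, "low"], ci_high = ci[, "high"],
                         call = call, row.names = NULL),
      chiSquare = chi, df = df, pValue = p, behavior = behavior,
      individual = as.character(individual), conf = conf)
}

#' Tabulate an individual's use of cover types
#'
#' Counts the reported (error-containing) fix locations of one behaviour per
#' cover type of a landscape.
#'
#' @param fixset a \linkS4class{FixSet}
#' @param landscape a \linkS4class{GridLandscape}
#' @param behavior `"nest"`, `"roost"` or `"forage"`
#' @return named integer vector of counts per cover type name
#' @export
tabulateUse <- function(fixset, landscape, behavior) {
  f <- fixes(fixset)
  f <- f[f$behavior == behavior, , drop = FALSE]
  g <- classGrid(landscape)
  idx <- cellAt(cbind(f$x_m, f$y_m), nrow(g), ncol(g), cellSize(landscape),
                gridOrigin(landscape))
  idx <- idx[!is.na(idx)]
  codes <- names(habitatLegend(landscape))
  tab <- table(factor(as.vector(g)[idx], levels = codes))
  setNames(as.integer(tab), habitatLegend(landscape)[codes])
}

#' Build the functional habitat map from selection tables
#'
#' Pools selection results across individuals: a cover typology is assigned
#' to a behaviour's functional class when a strict majority of the
#' individuals tested for that behaviour back it. An individual backs a
#' typology for foraging when its selection table calls the typology
#' selected; for nesting and roosting -- behaviours whose sites are directly
#' observed rather than inferred, and whose use-versus-availability test is
#' underpowered when the habitat class dominates the home range -- a typology
#' is also backed when it holds at least `placement_threshold` of the
#' behaviour's locations (a directly observed site cluster). A typology is
#' assigned when backed by a strict majority of the tested individuals
#' (primary habitat) or by at least `secondary_min` individuals (secondary
#' habitat used consistently by a minority, such as a crop type foraged in by
#' some birds only). A typology claimed by several behaviours goes to the one
#' with the highest vote share; exact ties and typologies never backed become
#' non-usable.
#'
#' @param tables list of \linkS4class{SelectionTable}s across individuals and
#'   behaviours (behaviours `"nesting"`, `"roosting"`, `"foraging"`)
#' @param structural the structural \linkS4class{GridLandscape} whose legend
#'   names the typologies
#' @param placement_threshold minimum share of a behaviour's locations for a
#'   placement-based vote (default 0.25; nesting and roosting only)
#' @param secondary_min minimum number of backing individuals for a
#'   secondary-habitat assignment short of a majority (default 2; a single
#'   individual's call never defines a class)
#' @return list with elements `assignment`
#'   (\linkS4class{FunctionalAssignment}) and `landscape` (the relabelled
#'   functional \linkS4class{GridLandscape})
#' @export
buildFunctionalMap <- function(tables, structural, placement_threshold = 0.25,
                               secondary_min = 2L) {
  if (!length(tables)) stop("empty table set")
  stopifnot(all(vapply(tables, is, logical(1), "SelectionTable")))
  legend <- habitatLegend(structural)
  behav_class <- c(nesting = 1L, roosting = 2L, foraging = 3L)
  votes <- data.frame()
  share <- matrix(0, nrow = length(legend), ncol = 3,
                  dimnames = list(unname(legend), names(behav_class)))
  for (b in names(behav_class)) {
    tb <- tables[vapply(tables, function(t) t@behavior == b, logical(1))]
    if (!length(tb)) next
    inds <- unique(vapply(tb, function(t) t@individual, character(1)))
    n_tested <- length(inds)
    placement <- b %in% c("nesting", "roosting")
    for (type in unname(legend)) {
      sel_by <- vapply(tb, function(t) {
        row <- t@table[t@table$cover_type == type, , drop = FALSE]
        if (!nrow(row)) return(FALSE)
        row$call == "selected" ||
          (placement && row$used_prop >= placement_threshold)
      }, logical(1))
      inds_sel <- unique(vapply(tb[sel_by], function(t) t@individual,
                                character(1)))
      v <- length(inds_sel)
      votes <- rbind(votes, data.frame(typology = type, behavior = b,
                                       votes = v, n_tested = n_tested))
      if (v > n_tested / 2 || v >= secondary_min) share[type, b] <- v / n_tested
    }
  }
  mapping <- setNames(rep(0L, length(legend)), names(legend))
  for (i in seq_len(nrow(share))) {
    s <- share[i, ]
    if (max(s) > 0 && sum(s == max(s)) == 1L)
      mapping[i] <- behav_class[[which.max(s)]]
  }
  g <- classGrid(structural)
  fun_grid <- matrix(mapping[as.character(g)], nrow(g), ncol(g))
  list(assignment = new("FunctionalAssignment", mapping = mapping,
                        votes = votes),
       landscape = GridLandscape(fun_grid, cellSize = cellSize(structural),
                                 origin = gridOrigin(structural),
                                 level = "functional"))
}

#' Fraction of usable habitat
#'
#' Fraction of cells of a functional landscape belonging to any usable class
#' (breeding, roosting or foraging).
#'
#' @param functional a functional-level \linkS4class{GridLandscape}
#' @return fraction in [0, 1]
#' @export
usableFraction <- function(functional) {
  stopifnot(is(functional, "GridLandscape"))
  if (landscapeLevel(functional) != "functional")
    stop("usableFraction() expects a functional-level landscape")
  mean(classGrid(functional) != 0L)
}
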