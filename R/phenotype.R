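#' Skin colour category scales
#'
#' The fixed, lightness-descending category orders used throughout the
#' package: five prediction categories (Very Pale, Pale, Intermediate, Dark,
#' Dark-Black), their three-category grouping (Light, Dark, Dark-Black),
#' and the spectrophotometer-derived three-level scale (White, Intermediate,
#' Black) used for L*-based phenotyping.
#'
#' @return character vector of category labels in fixed order.
#' @examples
#' skinCategories5()
#' @export
skinCategories5 <- function() {
  c("VeryPale", "Pale", "Intermediate", "Dark", "DarkBlack")
}

#' @rdname skinCategories5
#' @export
skinCategories3 <- function() c("Light", "Dark", "DarkBlack")

#' @rdname skinCategories5
#' @export
labCategories <- function() c("White", "Intermediate", "Black")

checkFitzpatrick <- function(ft) {
  if (any(is.na(ft)) || any(ft != as.integer(ft)) ||
      any(ft < 1L | ft > 6L))
    stop("Fitzpatrick skin type must be an integer in 1..6")
  as.integer(ft)
}

#' Map Fitzpatrick skin types to prediction categories
#'
#' The six dermatological Fitzpatrick skin types condense onto the five
#' prediction categories with types 3 and 4 merged into Intermediate
#' (1 -> Very Pale, 2 -> Pale, 3/4 -> Intermediate, 5 -> Dark, 6 ->
#' Dark-Black), and onto the three-category scale with types 1-4 grouped as
#' Light (5 -> Dark, 6 -> Dark-Black). Both maps are total on 1..6 and
#' vectorized.
#'
#' @param ft integer vector of Fitzpatrick skin types in 1..6.
#' @return factor over [skinCategories5()] (or [skinCategories3()]).
#' @examples
#' fitzpatrickTo5cat(1:6)
#' fitzpatrickTo3cat(4)  # Light
#' @export
fitzpatrickTo5cat <- function(ft) {
  ft <- checkFitzpatrick(ft)
  map <- c("VeryPale", "Pale", "Intermediate", "Intermediate", "Dark",
           "DarkBlack")
  factor(map[ft], levels = skinCategories5())
}

#' @rdname fitzpatrickTo5cat
#' @export
fitzpatrickTo3cat <- function(ft) {
  ft <- checkFitzpatrick(ft)
  map <- c("Light", "Light", "Light", "Light", "Dark", "DarkBlack")
  factor(map[ft], levels = skinCategories3())
}

#' Collapse five-category labels to the three-category scale
#'
#' Very Pale, Pale and Intermediate collapse into Light; Dark and
#' Dark-Black map to themselves. Composes with the Fitzpatrick maps:
#' \code{collapse5to3(fitzpatrickTo5cat(ft)) == fitzpatrickTo3cat(ft)}.
#'
#' @param x factor or character vector of five-category labels.
#' @return factor over [skinCategories3()].
#' @examples
#' collapse5to3(c("Pale", "Dark"))
#' @export
collapse5to3 <- function(x) {
  x <- as.character(x)
  bad <- !x %in% skinCategories5()
  if (any(bad)) stop("not a five-category label: ",
                     paste(unique(x[bad]), collapse = ", "))
  out <- ifelse(x %in% c("VeryPale", "Pale", "Intermediate"), "Light", x)
  factor(out, levels = skinCategories3())
}

#' CIE L* category thresholds
#'
#' The published L* ranges binning spectrophotometer readings into
#' White (60.36-74.14), Intermediate (40.04-59.32) and Black (29.99-39.75).
#' Ranges are inclusive at both endpoints, disjoint and descending in
#' lightness; the short gaps between ranges are handled by the
#' \code{nearest} mode of [labTo3cat()].
#'
#' @param white,intermediate,black numeric length-2 (lower, upper) bounds.
#' @return named list of ranges, validated.
#' @export
labThresholds <- function(white = c(60.36, 74.14),
                          intermediate = c(40.04, 59.32),
                          black = c(29.99, 39.75)) {
  th <- list(White = sort(white), Intermediate = sort(intermediate),
             Black = sort(black))
  if (!(th$White[1] > th$Intermediate[2] &&
        th$Intermediate[1] > th$Black[2]))
    stop("L* ranges must be disjoint and descending (White > Intermediate > Black)")
  th
}

#' Bin a CIE L* reading into White/Intermediate/Black
#'
#' Readings inside a published range take that range's category. Readings
#' in the unassigned gaps between ranges (or beyond the extremes) raise an
#' error in \code{strict} mode; in \code{nearest} mode they take the
#' category of the nearest range boundary (ties go to the lighter
#' category), which keeps the map monotone in L*.
#'
#' @param L numeric vector of L* values in (0, 100).
#' @param thresholds output of [labThresholds()].
#' @param mode \code{"strict"} or \code{"nearest"}.
#' @return factor over [labCategories()].
#' @examples
#' labTo3cat(c(65, 45, 35))
#' labTo3cat(60, mode = "nearest")  # gap value, nearest boundary is White's
#' @export
labTo3cat <- function(L, thresholds = labThresholds(),
                      mode = c("strict", "nearest")) {
  mode <- match.arg(mode)
  if (any(is.na(L)) || any(L <= 0 | L >= 100))
    stop("L* values must lie in (0, 100)")
  cats <- labCategories()
  out <- character(length(L))
  for (i in seq_along(L)) {
    inRange <- vapply(cats, function(cc)
      L[i] >= thresholds[[cc]][1] && L[i] <= thresholds[[cc]][2], logical(1))
    if (any(inRange)) {
      out[i] <- cats[which(inRange)[1]]
    } else if (mode == "strict") {
      stop(sprintf("L* = %g falls outside the published ranges (strict mode)",
                   L[i]))
    } else {
      bounds <- unlist(thresholds)
      dist <- abs(bounds - L[i])
      nearest <- names(bounds)[which(dist == min(dist))]
      # strip the "1"/"2" suffix unlist() appends to range endpoints
      nearest <- sub("[12]$", "", nearest)
      # ties between two categories resolve to the lighter one
      out[i] <- cats[min(match(nearest, cats))]
    }
  }
  factor(out, levels = cats)
}
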