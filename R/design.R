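#' Parse an experimental design into a DesignTable
#'
#' Reads a rectangular table of categorical factor columns, one row per
#' observation. Levels are enumerated in order of first appearance unless an
#' explicit ordering is supplied through `levelOrder`; the last level in the
#' resulting order is the one coded with -1 by [buildCoding()].
#'
#' @param table a data.frame (or anything coercible), or the path to a
#'   CSV/TSV file with a header row; every column is treated as a factor.
#' @param levelOrder optional named list, `factor = c("lvl1", "lvl2", ...)`,
#'   overriding the first-appearance level order for some factors.
#' @param sep field separator when `table` is a path; `""` auto-detects
#'   between comma and tab.
#' @return a [DesignTable-class].
#' @examples
#' d <- parseDesign(data.frame(temp = rep(c(10, 20, 30), each = 2)))
#' nObs(d)
#' @export
parseDesign <- function(table, levelOrder = NULL, sep = "") {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) stop("design file not found: ", table)
    if (!nzchar(sep)) {
      first <- readLines(table, n = 1L)
      sep <- if (grepl("\t", first)) "\t" else ","
    }
    table <- utils::read.table(table, header = TRUE, sep = sep,
                               colClasses = "character",
                               check.names = FALSE, strip.white = TRUE)
  }
  table <- as.data.frame(table)
  if (nrow(table) == 0L || ncol(table) == 0L)
    stop("empty design table: at least one observation and one factor column are required")
  if (is.null(colnames(table)) || any(!nzchar(colnames(table))))
    colnames(table) <- paste0("factor", seq_len(ncol(table)))
  n <- nrow(table)
  levels <- vector("list", ncol(table))
  names(levels) <- colnames(table)
  assignments <- matrix(NA_integer_, n, ncol(table),
                        dimnames = list(NULL, colnames(table)))
  for (f in seq_len(ncol(table))) {
    vals <- as.character(table[[f]])
    bad <- which(is.na(table[[f]]) | !nzchar(trimws(vals)))
    if (length(bad))
      stop(sprintf("missing level for factor '%s' at row %d",
                   colnames(table)[f], bad[1L]))
    lv <- unique(vals)
    if (!is.null(levelOrder[[colnames(table)[f]]])) {
      want <- as.character(levelOrder[[colnames(table)[f]]])
      if (!setequal(want, lv))
        stop(sprintf("levelOrder for factor '%s' does not match observed levels",
                     colnames(table)[f]))
      lv <- want
    }
    levels[[f]] <- lv
    assignments[, f] <- match(vals, lv)
  }
  new("DesignTable", assignments = assignments, levels = levels)
}

#' Balanced full-factorial design
#'
#' @param levels integer vector of level counts, one per factor (all >= 2).
#' @param replicates replicates per level combination (>= 1).
#' @param factorNames optional factor names (default F1, F2, ...).
#' @return a [DesignTable-class] with `replicates * prod(levels)`
#'   observations; every level combination appears exactly `replicates`
#'   times, replicates varying fastest.
#' @examples
#' nObs(fullFactorial(c(4, 3), 4))  # 48
#' @export
fullFactorial <- function(levels, replicates = 1L, factorNames = NULL) {
  levels <- as.integer(levels)
  if (length(levels) < 1L || any(levels < 2L))
    stop("every factor needs at least 2 levels")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is.null(factorNames)) factorNames <- paste0("F", seq_along(levels))
  grid <- expand.grid(c(list(rep = seq_len(replicates)),
                        stats::setNames(lapply(levels, seq_len), factorNames)),
                      KEEP.OUT.ATTRS = FALSE)
  df <- grid[factorNames]
  parseDesign(data.frame(lapply(df, function(v) sprintf("L%d", v)),
                         check.names = FALSE))
}

# Parse term labels into validated main/interaction structure.
# Terms are factor names or "A:B" pairs; interaction parents need not be
# listed themselves when onlyDeclared = FALSE.
.parseTerms <- function(terms, design) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate terms: ",
                                 paste(terms[duplicated(terms)], collapse = ", "))
  fn <- factorNames(design)
  parts <- strsplit(terms, ":", fixed = TRUE)
  ord <- lengths(parts)
  if (any(ord > 2L))
    stop("only two-way interactions are supported; offending term: ",
         terms[which(ord > 2L)[1L]])
  main <- terms[ord == 1L]
  unknown <- setdiff(unlist(parts), fn)
  if (length(unknown))
    stop("unknown factor(s) in terms: ", paste(unknown, collapse = ", "))
  for (p in parts[ord == 2L]) {
    if (p[1L] == p[2L]) stop("interaction of a factor with itself: ", p[1L])
    missing <- setdiff(p, main)
    if (length(missing))
      stop("interaction members must be declared main terms; missing: ",
           paste(missing, collapse = ", "))
  }
  list(labels = terms, parts = parts)
}

#' Build the sum/deviation coding matrix of a design
#'
#' For a factor with L levels, an observation at level l < L gets a 1 in
#' column l of the factor's block and 0 elsewhere; an observation at the last
#' level gets -1 in all L-1 columns. A two-way interaction block contains all
#' pairwise element-wise products of its parents' columns, hence
#' (L_A - 1)(L_B - 1) columns. The intercept is an all-ones column.
#'
#' @param design a [DesignTable-class].
#' @param terms character vector of term labels: factor names and optional
#'   `"A:B"` interactions (parents must be listed). Default: all factors.
#' @return a [CodingMatrix-class].
#' @examples
#' d <- fullFactorial(c(3, 2), 2, c("temp", "pH"))
#' C <- buildCoding(d, c("temp", "pH", "temp:pH"))
#' codingValues(C)[1, ]
#' @export
buildCoding <- function(design, terms = factorNames(design)) {
  stopifnot(is(design, "DesignTable"))
  tm <- .parseTerms(terms, design)
  n <- nObs(design)
  cols <- list(`(intercept)` = matrix(1, n, 1L))
  for (i in seq_along(tm$labels)) {
    p <- tm$parts[[i]]
    if (length(p) == 1L) {
      L <- length(design@levels[[p]])
      if (L < 2L)
        stop(sprintf("factor '%s' has a single level (zero df)", p))
      a <- design@assignments[, p]
      block <- matrix(0, n, L - 1L)
      for (l in seq_len(L - 1L)) block[a == l, l] <- 1
      block[a == L, ] <- -1
      cols[[tm$labels[i]]] <- block
    } else {
      bA <- cols[[p[1L]]]; bB <- cols[[p[2L]]]
      block <- matrix(0, n, ncol(bA) * ncol(bB))
      k <- 0L
      for (ia in seq_len(ncol(bA))) for (ib in seq_len(ncol(bB))) {
        k <- k + 1L
        block[, k] <- bA[, ia] * bB[, ib]
      }
      cols[[tm$labels[i]]] <- block
    }
  }
  widths <- vapply(cols, ncol, integer(1))
  ends <- cumsum(widths)
  blocks <- Map(function(e, w) seq.int(e - w + 1L, e), ends, widths)
  values <- do.call(cbind, cols)
  colnames(values) <- unlist(Map(function(nm, w)
    if (w == 1L) nm else paste0(nm, seq_len(w)), names(cols), widths))
  new("CodingMatrix", values = values, blocks = blocks,
      df = stats::setNames(as.integer(widths), names(cols)), design = design)
}

#' @rdname CodingMatrix-class
#' @param object a [CodingMatrix-class].
#' @export
codingValues <- function(object) object@values

#' @rdname CodingMatrix-class
#' @export
codingBlocks <- function(object) object@blocks

#' @rdname CodingMatrix-class
#' @export
termDf <- function(object) object@df

#' @rdname DesignTable-class
#' @export
setMethod("nObs", "DesignTable", function(object) nrow(object@assignments))

#' @rdname DesignTable-class
#' @export
setMethod("factorNames", "DesignTable", function(object) names(object@levels))

#' @rdname DesignTable-class
#' @export
setMethod("designLevels", "DesignTable", function(object) object@levels)

#' Design as a data.frame of factors
#' @param x a [DesignTable-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "DesignTable", function(x, ...) {
  out <- lapply(factorNames(x), function(f)
    factor(x@levels[[f]][x@assignments[, f]], levels = x@levels[[f]]))
  names(out) <- factorNames(x)
  as.data.frame(out, check.names = FALSE)
})

# One label per observation identifying its design cell (used for
# stratified bootstrap resampling).
.cellLabels <- function(design) {
  apply(design@assignments, 1L, paste, collapse = "/")
}

setMethod("show", "DesignTable", function(object) {
  cat(sprintf("DesignTable: %d observations, %d factor(s)\n",
              nObs(object), length(object@levels)))
  for (f in factorNames(object))
    cat(sprintf("  %s: %d levels (%s)\n", f, length(object@levels[[f]]),
                paste(object@levels[[f]], collapse = ", ")))
})

setMethod("show", "CodingMatrix", function(object) {
  cat(sprintf("CodingMatrix: %d x %d; terms: %s\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s (df=%d)", names(object@df), object@df),
                    collapse = ", ")))
})
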