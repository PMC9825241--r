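#' Read a measurement matrix from delimited text
#'
#' Rows are observations, columns are variables, header row holds variable
#' names. Separator auto-detected between comma and tab unless given.
#'
#' @param path CSV/TSV file path.
#' @param sep field separator (`""` auto-detects).
#' @return numeric matrix.
#' @export
readMatrixCSV <- function(path, sep = "") {
  if (!file.exists(path)) stop("data file not found: ", path)
  if (!nzchar(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric data column(s): ", paste(bad, collapse = ", "))
  as.matrix(df)
}

#' Run the full analysis pipeline on a dataset
#'
#' Factorize, test, visualize: fits the ASCA+ decomposition, then for every
#' term runs the ASCA whole-matrix test, VASCA, and optionally the FDR and
#' leverage/SPE baselines; for terms with a non-empty VASCA selection, fits
#' the effect-matrix PCA and bootstrap loading intervals. All randomness
#' derives from `seed`, which is recorded in the returned bundle together
#' with the full configuration, so any bundle re-runs to identical numbers.
#'
#' @param data numeric matrix or path to a CSV/TSV data file.
#' @param design [DesignTable-class], data.frame, or path to a design file.
#' @param terms term labels (default: all design factors).
#' @param statistic `"fratio"` or `"ssq"`.
#' @param preprocess preprocessing mode; defaults to `"autoscale"` (the
#'   usual ASCA practice, and mandatory for the ssq statistic) — with
#'   heterogeneous variable scales the summed-SSQ statistics of the
#'   whole-matrix and sub-matrix tests would otherwise be dominated by the
#'   high-variance variables.
#' @param nPerm permutations K.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param methods which methods to run alongside VASCA: subset of
#'   `"asca"`, `"fdr"`, `"asca_genes"`.
#' @param bootstrapB bootstrap resamples for loading intervals (0 disables).
#' @param outDir optional directory; when given, writes per-term CSV tables
#'   (VASCA curve, FDR table, leverage/SPE table, loadings) and a
#'   `summary.json` with the configuration and headline results.
#' @param levelOrder passed to [parseDesign()] when `design` is a file or
#'   data.frame.
#' @return a list bundle: `config`, `decomposition`, and per-term results
#'   (`asca`, `vasca`, `fdr`, `ascaGenes`, `components`, `bootstrap`).
#' @export
runAnalysis <- function(data, design, terms = NULL,
                        statistic = c("fratio", "ssq"), preprocess = NULL,
                        nPerm = 1000L, alpha = 0.05, seed = 1L,
                        methods = c("asca", "fdr"), bootstrapB = 1000L,
                        outDir = NULL, levelOrder = NULL) {
  statistic <- match.arg(statistic)
  if (length(methods))
    methods <- match.arg(methods, c("asca", "fdr", "asca_genes"),
                         several.ok = TRUE)
  if (is.character(data)) data <- readMatrixCSV(data)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (!is(design, "DesignTable")) design <- parseDesign(design, levelOrder)
  if (nrow(data) != nObs(design))
    stop(sprintf("data has %d rows but the design has %d observations",
                 nrow(data), nObs(design)))
  if (is.null(terms)) terms <- factorNames(design)
  if (is.null(preprocess)) preprocess <- "autoscale"
  if (statistic == "ssq" && preprocess != "autoscale")
    stop("the ssq statistic requires preprocess = \"autoscale\"")
  config <- list(terms = terms, statistic = statistic,
                 preprocess = preprocess, nPerm = as.integer(nPerm),
                 alpha = alpha, seed = as.integer(seed), methods = methods,
                 bootstrapB = as.integer(bootstrapB))

  coding <- buildCoding(design, terms)
  decomp <- fitGLM(data, coding, preprocess)
  plan <- permutationPlan(nPerm, seed)
  bundle <- list(config = config, decomposition = decomp, terms = list())
  for (t in terms) {
    res <- list()
    res$vasca <- vascaTest(decomp, t, statistic, plan, alpha)
    if ("asca" %in% methods)
      res$asca <- ascaTest(decomp, t, statistic, plan)
    if ("fdr" %in% methods)
      res$fdr <- fdrTest(decomp, t, statistic, plan, alpha)
    if ("asca_genes" %in% methods) {
      if (decomp@df[[t]] >= 2L)
        res$ascaGenes <- ascaGenesTest(decomp, t, plan, alpha = alpha)
      else
        message("asca_genes skipped for 1-df term '", t, "'")
    }
    sel <- selectedVariables(res$vasca)
    if (length(sel)) {
      res$components <- fitComponents(decomp, t, sel)
      if (bootstrapB >= 100L)
        res$bootstrap <- bootstrapLoadings(decomp, t, sel,
                                           B = bootstrapB, seed = seed,
                                           alpha = alpha)
    }
    bundle$terms[[t]] <- res
  }
  if (!is.null(outDir)) .writeBundle(bundle, outDir)
  bundle
}

# Serialize a bundle: per-term CSVs plus a JSON summary embedding the
# configuration (the reproducibility record).
.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(config = bundle$config, terms = list())
  for (t in names(bundle$terms)) {
    res <- bundle$terms[[t]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", t)
    v <- res$vasca
    tab <- as.data.frame(v@curve)
    tab$p <- v@pCurve[tab$m]
    utils::write.csv(tab, file.path(outDir, paste0("vasca_", safe, ".csv")),
                     row.names = FALSE)
    info <- list(vasca = list(selectedM = v@selectedM,
                              selected = v@selected,
                              wholeMatrixP = v@pCurve[length(v@pCurve)]))
    if (!is.null(res$asca)) info$asca <- list(p = pValue(res$asca))
    if (!is.null(res$fdr)) {
      utils::write.csv(
        data.frame(variable = seq_along(res$fdr@pRaw), p = res$fdr@pRaw,
                   pAdjusted = res$fdr@pAdjusted),
        file.path(outDir, paste0("fdr_", safe, ".csv")), row.names = FALSE)
      info$fdr <- list(significant = res$fdr@significant)
    }
    if (!is.null(res$ascaGenes)) {
      g <- res$ascaGenes
      utils::write.csv(
        data.frame(variable = seq_along(leverage(g)), leverage = leverage(g),
                   spe = spe(g), flag = as.character(g@flags)),
        file.path(outDir, paste0("asca_genes_", safe, ".csv")),
        row.names = FALSE)
      info$ascaGenes <- list(limits = as.list(g@limits))
    }
    if (!is.null(res$bootstrap))
      utils::write.csv(as.data.frame(res$bootstrap),
                       file.path(outDir, paste0("loadings_", safe, ".csv")),
                       row.names = FALSE)
    summary$terms[[t]] <- info
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Long-format p-value curves for plotting
#'
#' Combines VASCA p-curves and (clamped, ascending) BH-adjusted FDR
#' p-values into the long table behind the ordered p-value figures: one row
#' per (method, rank m). ASCA contributes its single whole-matrix p at
#' m = M. Reference significance levels are attached as the
#' `"referenceLevels"` attribute.
#'
#' @param termResults one term's entry of a [runAnalysis()] bundle (a list
#'   possibly holding `vasca`, `fdr`, `asca`).
#' @return data.frame (method, m, p), sorted by method then m.
#' @export
exportPcurve <- function(termResults) {
  rows <- list()
  if (!is.null(termResults$vasca))
    rows$vasca <- data.frame(method = "vasca",
                             m = seq_along(termResults$vasca@pCurve),
                             p = termResults$vasca@pCurve)
  if (!is.null(termResults$fdr))
    rows$fdr <- data.frame(method = "fdr",
                           m = seq_along(termResults$fdr@pAdjusted),
                           p = pmin(sort(termResults$fdr@pAdjusted), 1))
  if (!is.null(termResults$asca)) {
    mAsca <- if (!is.null(termResults$vasca))
      length(termResults$vasca@pCurve)
    else if (!is.null(termResults$fdr)) length(termResults$fdr@pAdjusted)
    else NA_integer_
    rows$asca <- data.frame(method = "asca", m = mAsca,
                            p = pValue(termResults$asca))
  }
  if (!length(rows)) stop("no VASCA or FDR results present")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$method, out$m), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "referenceLevels") <- c(0.05, 0.01)
  out
}
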