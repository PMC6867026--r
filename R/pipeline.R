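#' Run the full median pipeline
#'
#' Orchestrates the end-to-end analysis: optionally reduce by unanimously
#' shared features, compute the generalized median, verify its guaranteed
#' properties, and (when the median is not genomic) recover a genome by the
#' requested heuristic, restoring everything to the original extremity set.
#'
#' @param a,b,c [genome()] objects, or `genomes` a list of three.
#' @param genomes Optional list of three [genome()] objects (alternative to
#'   `a`, `b`, `c`).
#' @param reduce Remove unanimously shared features first (default `TRUE`).
#' @param method Recovery method when the median is not genomic:
#'   `"auto"` (closest-genome where applicable, falling back to matching,
#'   reporting both when both run), `"closest"`, `"matching"`, or `"none"`.
#' @param exact Use exact integer arithmetic for the median.
#' @param max_block Component-size limit for the closest-genome search.
#' @param tol,rank_tol Entry and rank tolerances.
#' @param report_path Optional path; when given, the report is also written
#'   as JSON.
#' @return A list report: `invariants` (alpha, beta, delta), `dims`,
#'   `score`, `is_genomic`, `median` (matrix on the original extremity set),
#'   `genome` (cycle string of the median or recovered genome), `recovery`
#'   (method, score, gap — `NULL` when the median is genomic), `conserved`,
#'   `diagnostics`, `reduced_n`, and `timings` (seconds).
#' @export
run_median_pipeline <- function(a = NULL, b = NULL, c = NULL, genomes = NULL,
                                reduce = TRUE, method = c("auto", "closest",
                                                          "matching", "none"),
                                exact = FALSE, max_block = 10L, tol = 1e-6,
                                rank_tol = 1e-9, report_path = NULL) {
  method <- match.arg(method)
  if (!is.null(genomes)) {
    stopifnot(length(genomes) == 3L)
    a <- genomes[[1L]]; b <- genomes[[2L]]; c <- genomes[[3L]]
  }
  stopifnot(is_genome(a), is_genome(b), is_genome(c))
  t0 <- proc.time()[["elapsed"]]
  inv <- median_invariants(a, b, c)
  dims <- subspace_dims(a, b, c)
  red <- if (reduce) reduce_unanimous(a, b, c) else
    list(a = a, b = b, c = c, kept = seq_len(a$n), fixed = list(),
         n_original = a$n)
  t1 <- proc.time()[["elapsed"]]
  if (red$a$n == 0L) {
    # inputs identical: the unique median is the common genome
    g <- a
    m <- genome_to_matrix(g)
    med <- NULL
    is_genomic <- TRUE
    score <- 0L
    diagnostics <- c(0L, 0L, 0L)
    conserved <- check_conservation(a, b, c, m, tol)
  } else {
    med <- compute_median(red$a, red$b, red$c, exact = exact, tol = tol,
                          rank_tol = rank_tol)
    m <- restore_matrix(med$m, red$kept, red$fixed, red$n_original)
    is_genomic <- med$is_genomic
    g <- if (is_genomic)
      restore_genome(med$genome, red$kept, red$fixed, red$n_original)
    score <- median_score(m, a, b, c, tol = rank_tol)
    stopifnot("restored median does not attain beta" = score == inv$beta)
    diagnostics <- med$diagnostics
    conserved <- check_conservation(a, b, c, m, tol)
  }
  t2 <- proc.time()[["elapsed"]]
  recovery <- NULL
  if (!is_genomic && method != "none") {
    run_closest <- method %in% c("auto", "closest")
    run_matching <- method %in% c("auto", "matching")
    closest <- NULL
    if (run_closest) {
      closest <- tryCatch(
        closest_genome_heuristic(med$m, red$a, red$b, red$c,
                                 max_block = max_block, tol = tol,
                                 rank_tol = rank_tol),
        error = function(e) {
          if (method == "closest") stop(e)
          NULL
        })
    }
    matched <- NULL
    if (run_matching || (method == "auto" && is.null(closest))) {
      gm <- matching_heuristic(med$m, eps = tol)
      sm <- median_score(gm, red$a, red$b, red$c)
      matched <- list(genome = gm, score = sm, gap = sm - med$invariants$beta,
                      method = "matching")
    }
    pick <- if (!is.null(closest) &&
                (is.null(matched) || closest$score <= matched$score))
      closest else matched
    g <- restore_genome(pick$genome, red$kept, red$fixed, red$n_original)
    recovery <- list(method = pick$method,
                     score = median_score(g, a, b, c),
                     gap = median_score(g, a, b, c) - inv$beta,
                     genome = format_cycles(g),
                     matching = if (!is.null(matched))
                       list(score = matched$score, gap = matched$gap),
                     closest = if (!is.null(closest))
                       list(score = closest$score, gap = closest$gap))
  }
  t3 <- proc.time()[["elapsed"]]
  report <- list(
    n = a$n,
    invariants = list(alpha = inv$alpha, beta = inv$beta, delta = inv$delta,
                      d_ab = inv$d_ab, d_bc = inv$d_bc, d_ca = inv$d_ca),
    dims = dims,
    reduced_n = red$a$n,
    score = score,
    is_genomic = is_genomic,
    diagnostics = diagnostics,
    conserved = conserved,
    genome = if (!is.null(g)) format_cycles(g),
    recovery = recovery,
    median = m,
    timings = list(reduce = t1 - t0, median = t2 - t1, recover = t3 - t2)
  )
  if (!is.null(report_path)) {
    out <- report
    out$median <- NULL
    out$conserved <- as.list(conserved)
    jsonlite::write_json(out, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

#' Write a matrix as TSV
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a matrix from TSV
#'
#' @param path Input path.
#' @return A numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
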