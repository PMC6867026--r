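#' Construct a genome from an involution
#'
#' A genome on `n` gene extremities is an involution of `{1..n}`: 2-cycles are
#' adjacencies (two extremities glued together), fixed points are telomeres.
#'
#' @param pairing Integer vector of length `n`; `pairing[i]` is the extremity
#'   paired with `i` (equal to `i` for a telomere).
#' @param name Optional label.
#' @param warn_odd Warn when `n` is odd (an odd extremity count cannot come
#'   from whole genes, though all computations still apply). Internal
#'   reconstructions pass `FALSE` so the warning fires once per user input.
#' @return An object of class `"genome"` with fields `n`, `pairing`, `name`.
#' @examples
#' g <- genome(c(2L, 1L, 3L))  # adjacency {1,2}, telomere 3
#' adjacencies(g)
#' @export
genome <- function(pairing, name = NULL, warn_odd = TRUE) {
  pairing <- as.integer(pairing)
  n <- length(pairing)
  if (n > 0L) {
    if (anyNA(pairing) || any(pairing < 1L) || any(pairing > n))
      stop("pairing values must lie in 1..", n)
    if (any(pairing[pairing] != seq_len(n)))
      stop("not genomic: pairing is not an involution")
  }
  if (warn_odd && n %% 2L == 1L)
    warning("odd number of extremities (", n, "): not a whole-gene genome")
  structure(list(n = n, pairing = pairing, name = name), class = "genome")
}

is_genome <- function(x) inherits(x, "genome")

#' @export
print.genome <- function(x, ...) {
  lab <- if (is.null(x$name)) "genome" else paste0("genome '", x$name, "'")
  cat(lab, "on", x$n, "extremities:",
      if (x$n == 0L) "(empty)" else format_cycles(x), "\n")
  invisible(x)
}

#' @export
`==.genome` <- function(e1, e2) {
  e1$n == e2$n && all(e1$pairing == e2$pairing)
}

#' Adjacencies and telomeres of a genome
#'
#' @param g A [genome()].
#' @return `adjacencies()`: a two-column integer matrix (each row an unordered
#'   pair, smaller extremity first, rows sorted); `telomeres()`: an integer
#'   vector of fixed points.
#' @export
adjacencies <- function(g) {
  stopifnot(is_genome(g))
  i <- which(g$pairing > seq_len(g$n))
  cbind(a = i, b = g$pairing[i])
}

#' @rdname adjacencies
#' @export
telomeres <- function(g) {
  stopifnot(is_genome(g))
  which(g$pairing == seq_len(g$n))
}

#' Format a genome in disjoint-cycle notation
#'
#' @param g A [genome()].
#' @return A string such as `"(2 4)(3 9)"`; `"()"` for an all-telomere genome.
#' @export
format_cycles <- function(g) {
  adj <- adjacencies(g)
  if (nrow(adj) == 0L) return("()")
  paste0("(", adj[, 1L], " ", adj[, 2L], ")", collapse = "")
}

#' Parse a genome from cycle notation
#'
#' Accepts whitespace-tolerant products of disjoint cycles of length 1 or 2,
#' e.g. `"(2 4)(3 9)(6 8)(10 11)"`. Extremities not listed become telomeres.
#' Inside parentheses, elements are separated by whitespace or commas. A
#' separator-free multi-digit group such as `"(24)"` is read as a single
#' extremity when that index is in range, and otherwise split into single
#' digits (so `"(24)"` with `n = 12` means the adjacency `{2,4}`).
#'
#' @param text Cycle-notation string; `""` gives the all-telomere genome.
#' @param n Number of extremities (must be supplied: trailing telomeres are
#'   invisible in cycle notation).
#' @param name Optional label.
#' @return A [genome()].
#' @examples
#' parse_cycles("(2 4)(3 9)(6 8)(10 11)", n = 12)
#' @export
parse_cycles <- function(text, n, name = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 0L)
  text <- gsub("\\s+", " ", trimws(text))
  pairing <- seq_len(n)
  seen <- logical(n)
  if (nzchar(text)) {
    if (!grepl("^(\\s*\\([^()]*\\)\\s*)+$", text))
      stop("malformed cycle notation: ", sQuote(text))
    groups <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1L]]
    for (grp in groups) {
      inner <- trimws(substr(grp, 2L, nchar(grp) - 1L))
      if (!nzchar(inner)) next
      toks <- strsplit(inner, "[ ,]+")[[1L]]
      if (length(toks) == 1L && nchar(toks) > 1L &&
          suppressWarnings(as.integer(toks)) > n) {
        toks <- strsplit(toks, "")[[1L]]  # compact form, e.g. "(24)"
      }
      idx <- suppressWarnings(as.integer(toks))
      if (anyNA(idx)) stop("non-numeric cycle element in ", sQuote(grp))
      if (length(idx) > 2L)
        stop("not genomic: cycle of length ", length(idx), " in ", sQuote(grp))
      if (any(idx < 1L) || any(idx > n))
        stop("extremity out of range 1..", n, " in ", sQuote(grp))
      if (any(seen[idx]) || anyDuplicated(idx))
        stop("not a matching: extremity ",
             idx[which(seen[idx] | duplicated(idx))[1L]], " repeated")
      seen[idx] <- TRUE
      if (length(idx) == 2L) {
        pairing[idx[1L]] <- idx[2L]
        pairing[idx[2L]] <- idx[1L]
      }
    }
  }
  genome(pairing, name = name)
}

#' Genomic matrix of a genome
#'
#' The genomic matrix is the permutation matrix of the involution: binary,
#' symmetric and orthogonal, with `M[i, j] = 1` iff extremities `i` and `j`
#' are paired (diagonal ones are telomeres). Row and column sums are all 1.
#'
#' @param g A [genome()].
#' @return An `n x n` numeric 0/1 matrix.
#' @export
genome_to_matrix <- function(g) {
  stopifnot(is_genome(g))
  m <- matrix(0, g$n, g$n)
  if (g$n > 0L) m[cbind(seq_len(g$n), g$pairing)] <- 1
  m
}

#' Recover a genome from a matrix
#'
#' Inverse of [genome_to_matrix()]: succeeds only when every entry is within
#' `tol` of 0 or 1 and the rounded matrix is a valid genomic matrix
#' (symmetric, orthogonal, unit row sums). Used to decide whether a computed
#' median is itself genomic.
#'
#' @param m A square numeric matrix.
#' @param tol Entry tolerance (default `1e-6`).
#' @param name Optional label for the result.
#' @return A [genome()], or an error `"not genomic"` naming offending entries.
#' @export
matrix_to_genome <- function(m, tol = 1e-6, name = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  off <- which(pmin(abs(m), abs(m - 1)) > tol, arr.ind = TRUE)
  if (nrow(off) > 0L) {
    show <- utils::head(off, 3L)
    stop("not genomic: non-binary entries at ",
         paste0("(", show[, 1L], ",", show[, 2L], ")", collapse = ", "),
         if (nrow(off) > 3L) ", ..." else "")
  }
  b <- round(m)
  if (any(abs(b - t(b)) > 0)) stop("not genomic: matrix is not symmetric")
  if (any(rowSums(b) != 1) || any(colSums(b) != 1))
    stop("not genomic: row/column sums differ from 1")
  pairing <- apply(b, 1L, which.max)
  genome(as.integer(pairing), name = name)
}

#' Read and write genome files
#'
#' Two plain-text formats are supported. `"cycles"`: a header line `#n=<int>`
#' followed by one genome per line, `name<TAB>cycles` (cycles as in
#' [parse_cycles()]). `"adjacency-tsv"`: a header line `#n=<int>`, a column
#' header `genome extremity_a extremity_b` (tab-separated), then one row per
#' adjacency; a telomere row repeats the extremity in both columns; extremities
#' never mentioned are telomeres.
#'
#' @param path File path.
#' @param format `"cycles"` or `"adjacency-tsv"`.
#' @param genomes For `write_genomes()`, a list of [genome()] objects with a
#'   common `n`.
#' @return `read_genomes()`: a named list of [genome()] objects.
#' @export
read_genomes <- function(path, format = c("cycles", "adjacency-tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  hdr <- grep("^#n=", lines)
  if (length(hdr) != 1L)
    stop("missing '#n=<int>' header line in ", path)
  n <- as.integer(sub("^#n=\\s*", "", lines[hdr]))
  if (is.na(n)) stop("unreadable '#n=' header in ", path)
  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (format == "cycles") {
    out <- list()
    for (k in body_idx) {
      parts <- strsplit(lines[k], "\t")[[1L]]
      if (length(parts) < 1L || length(parts) > 2L)
        stop("line ", k, ": expected 'name<TAB>cycles'")
      nm <- if (length(parts) == 2L) parts[1L] else paste0("genome", length(out) + 1L)
      cyc <- if (length(parts) == 2L) parts[2L] else parts[1L]
      g <- tryCatch(parse_cycles(cyc, n, name = nm),
                    error = function(e) stop("line ", k, ": ", conditionMessage(e)))
      out[[nm]] <- g
    }
  } else {
    body_idx <- setdiff(body_idx, grep("^genome\t", lines))
    tab <- utils::read.delim(text = lines[body_idx], header = FALSE,
                             col.names = c("genome", "extremity_a", "extremity_b"),
                             stringsAsFactors = FALSE)
    out <- list()
    for (nm in unique(tab$genome)) {
      rows <- tab[tab$genome == nm, , drop = FALSE]
      pairing <- seq_len(n)
      seen <- logical(n)
      for (r in seq_len(nrow(rows))) {
        i <- rows$extremity_a[r]; j <- rows$extremity_b[r]
        if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > n || j > n)
          stop("genome ", sQuote(nm), ": extremity out of range 1..", n)
        if (seen[i] || (i != j && seen[j]))
          stop("genome ", sQuote(nm), ": not a matching: extremity repeated")
        seen[c(i, j)] <- TRUE
        pairing[i] <- j; pairing[j] <- i
      }
      out[[nm]] <- genome(pairing, name = nm)
    }
  }
  out
}

#' @rdname read_genomes
#' @export
write_genomes <- function(genomes, path, format = c("cycles", "adjacency-tsv")) {
  format <- match.arg(format)
  stopifnot(length(genomes) >= 1L, all(vapply(genomes, is_genome, TRUE)))
  n <- genomes[[1L]]$n
  stopifnot(all(vapply(genomes, function(g) g$n, 0L) == n))
  nms <- vapply(seq_along(genomes), function(k) {
    nm <- genomes[[k]]$name
    if (is.null(nm)) names(genomes)[k] %||% paste0("genome", k) else nm
  }, "")
  if (format == "cycles") {
    lines <- c(paste0("#n=", n),
               paste0(nms, "\t", vapply(genomes, format_cycles, "")))
  } else {
    rows <- character(0)
    for (k in seq_along(genomes)) {
      adj <- adjacencies(genomes[[k]])
      tel <- telomeres(genomes[[k]])
      rows <- c(rows,
                if (nrow(adj)) paste(nms[k], adj[, 1L], adj[, 2L], sep = "\t"),
                if (length(tel)) paste(nms[k], tel, tel, sep = "\t"))
    }
    lines <- c(paste0("#n=", n), "genome\textremity_a\textremity_b", rows)
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a
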