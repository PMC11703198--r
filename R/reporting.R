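# Aggregation of per-library screens into the primary-by-secondary
# interaction matrix, E-value filtering, and figure rendering.

#' Build the interaction matrix from per-library screens
#'
#' Each cell `(library, secondary)` holds the pair E-value of that library's
#' significant result for the secondary motif; pairs that were not
#' significant are left empty (distinct from an E-value of 1).
#'
#' @param runs Named list of `spice_screen` objects (or data.frames with
#'   columns `secondary` and `evalue`); names are the library / primary
#'   identifiers and must be unique.
#' @param motif_names Optional full set of column (secondary motif) names;
#'   defaults to the union observed across runs.
#' @return An object of class `interaction_matrix`: list with `cells`
#'   (data.frame `row`, `col`, `evalue`), `rows`, `cols`.
#' @export
build_matrix <- function(runs, motif_names = NULL) {
  if (is.null(names(runs)) || any(names(runs) == ""))
    stop("runs must be a named list (library identifiers)")
  if (anyDuplicated(names(runs)))
    stop("duplicate library id(s): ",
         paste(unique(names(runs)[duplicated(names(runs))]), collapse = ", "))
  cells <- do.call(rbind, lapply(names(runs), function(lib) {
    r <- runs[[lib]]
    tab <- if (inherits(r, "spice_screen")) r$significant else r
    if (!nrow(tab)) return(NULL)
    data.frame(row = lib, col = tab$secondary, evalue = tab$evalue,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cells))
    cells <- data.frame(row = character(), col = character(),
                        evalue = numeric(), stringsAsFactors = FALSE)
  if (any(cells$evalue <= 0)) stop("E-values must be positive")
  cols <- if (is.null(motif_names)) sort(unique(cells$col)) else motif_names
  structure(list(cells = cells, rows = names(runs), cols = cols),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> ", length(x$rows), " x ", length(x$cols),
      " (", nrow(x$cells), " populated cells)\n", sep = "")
  invisible(x)
}

#' @export
dim.interaction_matrix <- function(x) c(length(x$rows), length(x$cols))

#' Dense matrix view
#'
#' @param x An `interaction_matrix`.
#' @param transform `"evalue"` for raw E-values (`NA` where empty) or
#'   `"neglog10"` for `-log10(E)` with E-values floored at 1e-300.
#' @param ... Unused.
#' @return A numeric matrix with library rows and motif columns.
#' @method as.matrix interaction_matrix
#' @export
as.matrix.interaction_matrix <- function(x, transform = c("evalue",
                                                          "neglog10"), ...) {
  transform <- match.arg(transform)
  m <- matrix(NA_real_, length(x$rows), length(x$cols),
              dimnames = list(x$rows, x$cols))
  if (nrow(x$cells))
    m[cbind(match(x$cells$row, x$rows), match(x$cells$col, x$cols))] <-
      x$cells$evalue
  if (transform == "neglog10") m <- -log10(pmax(m, 1e-300))
  m
}

#' Filter the interaction matrix by E-value
#'
#' Drops cells with `evalue >= e_threshold`, then drops rows and columns
#' left without any populated cell.
#'
#' @param m An `interaction_matrix`.
#' @param e_threshold Keep cells strictly below this E-value (default
#'   1e-10).
#' @return A filtered `interaction_matrix`.
#' @export
filter_matrix <- function(m, e_threshold = 1e-10) {
  stopifnot(inherits(m, "interaction_matrix"))
  if (e_threshold <= 0) stop("e_threshold must be > 0")
  cells <- m$cells[m$cells$evalue < e_threshold, , drop = FALSE]
  structure(list(cells = cells,
                 rows = m$rows[m$rows %in% cells$row],
                 cols = m$cols[m$cols %in% cells$col]),
            class = "interaction_matrix")
}

#' Write / read the interaction matrix as sparse TSV
#'
#' Three columns `library`, `motif`, `evalue`; E-values are written with 17
#' significant digits so the decimal round-trip is exact.
#'
#' @param m An `interaction_matrix`.
#' @param path File path.
#' @return `path` (write) or an `interaction_matrix` (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(library = m$cells$row, motif = m$cells$col,
                   evalue = sprintf("%.17g", m$cells$evalue))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rows: ", paste(m$rows, collapse = ",")), con)
  writeLines(paste0("# cols: ", paste(m$cols, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- strsplit(sub("^# rows: ", "", lines[1]), ",")[[1]]
  cols <- strsplit(sub("^# cols: ", "", lines[2]), ",")[[1]]
  body <- lines[-(1:2)]
  if (length(body) > 1L) {
    df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "numeric"))
    cells <- data.frame(row = df$library, col = df$motif,
                        evalue = df$evalue, stringsAsFactors = FALSE)
  } else {
    cells <- data.frame(row = character(), col = character(),
                        evalue = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(cells = cells, rows = rows, cols = cols),
            class = "interaction_matrix")
}

#' Render the interaction heat map
#'
#' Cells are colored by `-log10(E-value)` (E-values floored at 1e-300);
#' empty cells take the background color so "not significant" is visually
#' distinct from "E-value near 1". Output is deterministic for fixed input.
#'
#' @param m An `interaction_matrix`.
#' @param file Output PNG path.
#' @param width,height,res Device geometry passed to [grDevices::png()].
#' @return `file`, invisibly.
#' @export
plot_heatmap <- function(m, file, width = 1200, height = 900, res = 150) {
  stopifnot(inherits(m, "interaction_matrix"))
  if (!nrow(m$cells))
    stop("interaction matrix is empty: relax the E-value filter")
  z <- as.matrix(m, transform = "neglog10")
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#fff5f0", "#fb6a4a", "#67000d"))(64)
  graphics::par(mar = c(7, 7, 2, 5))
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "motif pair interactions (-log10 E-value)")
  graphics::axis(1, seq_len(ncol(z)), colnames(z), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(z)), rownames(z), las = 2, cex.axis = 0.6)
  graphics::box()
  invisible(file)
}

#' Render the spacing bar graph of a pair result to a file
#'
#' @param pair A `spice_pair` from [analyze_pair()].
#' @param file Output PNG path.
#' @param width,height,res Device geometry.
#' @param ... Passed to [plot.spice_pair()].
#' @return `file`, invisibly.
#' @export
plot_spacing_bars <- function(pair, file, width = 1000, height = 600,
                              res = 150, ...) {
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot(pair, ...)
  invisible(file)
}
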