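#' Read a tabular expression matrix and class labels
#'
#' Ingests the package's tab-separated exchange format: a matrix with a
#' header row of sample names and a first column of probe or gene
#' identifiers, plus a two-column label file (`sample`, `class`). Samples
#' without a label are dropped with a message; lines starting with `#` are
#' ignored in both files. Exported GEO series-matrix tables fit this format
#' after trimming their metadata block.
#'
#' @param path Expression matrix file.
#' @param label_path Label file (`sample` TAB `class`, header optional).
#' @param species Provenance tag for the experiment.
#' @param classes Optional class-order override, see
#'   [two_class_experiment()].
#' @return A [two_class_experiment()].
#' @export
read_expression_table <- function(path, label_path, species = "unknown",
                                  classes = NULL) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) {
    stop("parse error in ", path, ": need an id column plus >= 2 samples",
         call. = FALSE)
  }
  sample_names <- colnames(tab)[-1]
  dup <- sample_names[duplicated(sample_names)]
  if (length(dup) > 0) {
    stop("parse error in ", path, ": duplicated sample column(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (j in seq(2, ncol(tab))) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))) &
                     !is.na(tab[[j]]))[1]
      stop("parse error in ", path, ": non-numeric value at row ", bad,
           ", column '", colnames(tab)[j], "'", call. = FALSE)
    }
  }
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- as.character(tab[[1]])

  lab <- utils::read.delim(label_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2) {
    stop("parse error in ", label_path,
         ": expected two tab-separated columns (sample, class)",
         call. = FALSE)
  }
  if (identical(tolower(lab[1, 1]), "sample")) lab <- lab[-1, , drop = FALSE]
  labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  two_class_experiment(expr, labels, species = species, classes = classes)
}

#' Write a two-class experiment to the tabular exchange format
#'
#' Inverse of [read_expression_table()]: writes the expression matrix (15
#' significant digits, so round trips are lossless to 12+ digits) and the
#' label file.
#'
#' @param exp A [two_class_experiment()].
#' @param path Expression matrix file to write.
#' @param label_path Label file to write.
#' @export
write_expression_table <- function(exp, path, label_path) {
  stopifnot(inherits(exp, "two_class_experiment"))
  sn <- colnames(exp$expr)
  if (is.null(sn)) sn <- paste0("sample", seq_len(ncol(exp$expr)))
  header <- paste(c("gene_id", sn), collapse = "\t")
  body <- vapply(seq_len(nrow(exp$expr)), function(i) {
    paste(c(rownames(exp$expr)[i], sprintf("%.15g", exp$expr[i, ])),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  writeLines(c("sample\tclass", paste(sn, as.character(exp$labels),
                                      sep = "\t")), label_path)
  invisible(path)
}

#' Collapse probe sets to genes by maximum variance
#'
#' Microarray platforms often carry several probe sets per gene; the probe
#' set with the largest expression variance across all samples of the data
#' set is kept as the gene's representative. Ties are broken by the
#' lexicographically smallest probe identifier; probes without a symbol
#' annotation are dropped.
#'
#' @param expr Numeric matrix, probes in rows (rownames are probe ids).
#' @param annotation Data frame with columns `probe_id`, `symbol`.
#' @return Matrix with one row per symbol (rownames are symbols).
#' @export
collapse_probesets <- function(expr, annotation) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            all(c("probe_id", "symbol") %in% names(annotation)))
  ann <- annotation[!is.na(annotation$symbol) & annotation$symbol != "", ]
  ann <- ann[ann$probe_id %in% rownames(expr), ]
  if (nrow(ann) == 0) {
    warning("no annotated probes: empty collapsed matrix", call. = FALSE)
    return(expr[0, , drop = FALSE])
  }
  v <- apply(expr[ann$probe_id, , drop = FALSE], 1, stats::var)
  picked <- tibble::tibble(probe_id = ann$probe_id, symbol = ann$symbol,
                           variance = unname(v)) |>
    dplyr::arrange(dplyr::desc(.data$variance), .data$probe_id) |>
    dplyr::distinct(.data$symbol, .keep_all = TRUE)
  out <- expr[picked$probe_id, , drop = FALSE]
  rownames(out) <- picked$symbol
  out
}

#' Read and resolve an ortholog symbol map
#'
#' Reads a two-column tab-separated table of model-organism symbol /
#' target (human) symbol pairs. Many-to-many entries are tolerated in the
#' file and resolved to a one-to-one map: for each symbol the partner whose
#' symbol matches case-insensitively is preferred (the mouse/human
#' Title-case vs UPPER-case convention), otherwise the lexicographically
#' first partner is kept.
#'
#' @param path File with columns `model_symbol`, `target_symbol` (header
#'   optional, `#` comments ignored).
#' @return Tibble with columns `model_symbol`, `target_symbol`, one-to-one
#'   in both directions.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    stop("parse error in ", path, ": expected two tab-separated columns",
         call. = FALSE)
  }
  if (identical(tolower(tab[1, 1]), "model_symbol")) {
    tab <- tab[-1, , drop = FALSE]
  }
  resolve_ortholog_map(tibble::tibble(model_symbol = as.character(tab[[1]]),
                                      target_symbol = as.character(tab[[2]])))
}

#' @rdname read_ortholog_map
#' @param map Tibble with columns `model_symbol`, `target_symbol`, possibly
#'   many-to-many.
#' @export
resolve_ortholog_map <- function(map) {
  stopifnot(all(c("model_symbol", "target_symbol") %in% names(map)))
  map |>
    dplyr::distinct(.data$model_symbol, .data$target_symbol) |>
    dplyr::mutate(case_match = tolower(.data$model_symbol) ==
                    tolower(.data$target_symbol)) |>
    dplyr::arrange(dplyr::desc(.data$case_match), .data$target_symbol) |>
    dplyr::distinct(.data$model_symbol, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$case_match), .data$model_symbol) |>
    dplyr::distinct(.data$target_symbol, .keep_all = TRUE) |>
    dplyr::select("model_symbol", "target_symbol")
}

#' Join model and target experiments on orthologous genes
#'
#' Computes per-gene statistics for both experiments (see
#' [compute_gene_stats()]) and inner-joins them through a resolved ortholog
#' map. Genes without a partner on the other side are dropped with a
#' message. The pair is keyed by the target (human) symbol.
#'
#' @param model_exp,target_exp [two_class_experiment()]s, gene-collapsed.
#' @param map Resolved ortholog map (see [read_ortholog_map()]). `NULL`
#'   joins directly on shared gene ids (useful when both sides already use
#'   one symbol space).
#' @param case_insensitive Also match symbols case-insensitively through
#'   the map (mouse `Il1rn` to human `IL1RN`); default `TRUE`.
#' @param sd_floor Passed to [compute_gene_stats()].
#' @return Tibble with one row per ortholog pair: `gene_id` (target
#'   symbol), `model_symbol`, model statistics (`f_m`, `s_m`, `n1_m`,
#'   `n2_m`, `dir_m`) and target statistics (`f_t`, `s_t`, `n1_t`, `n2_t`,
#'   `dir_t`).
#' @export
join_orthologs <- function(model_exp, target_exp, map = NULL,
                           case_insensitive = TRUE, sd_floor = 1e-6) {
  ms <- compute_gene_stats(model_exp, sd_floor = sd_floor)
  ts <- compute_gene_stats(target_exp, sd_floor = sd_floor)
  if (is.null(map)) {
    map <- tibble::tibble(model_symbol = ms$gene_id,
                          target_symbol = ms$gene_id)
  }
  key_m <- if (case_insensitive) tolower(ms$gene_id) else ms$gene_id
  key_t <- if (case_insensitive) tolower(ts$gene_id) else ts$gene_id
  map_km <- if (case_insensitive) tolower(map$model_symbol) else map$model_symbol
  map_kt <- if (case_insensitive) tolower(map$target_symbol) else map$target_symbol

  im <- match(map_km, key_m)
  it <- match(map_kt, key_t)
  keep <- !is.na(im) & !is.na(it)
  if (!any(keep)) {
    stop("configuration error: empty ortholog join; example model symbols: ",
         paste(utils::head(ms$gene_id, 3), collapse = ", "),
         "; example target symbols: ",
         paste(utils::head(ts$gene_id, 3), collapse = ", "), call. = FALSE)
  }
  n_dropped <- (nrow(ms) - sum(keep)) + (nrow(ts) - sum(keep))
  message("ortholog join: ", sum(keep), " pairs; ", nrow(ms) - sum(keep),
          " model and ", nrow(ts) - sum(keep),
          " target gene(s) without a partner dropped")
  im <- im[keep]
  it <- it[keep]
  tibble::tibble(
    gene_id = ts$gene_id[it],
    model_symbol = ms$gene_id[im],
    f_m = ms$f[im], s_m = ms$s[im], n1_m = ms$n1[im], n2_m = ms$n2[im],
    dir_m = ms$direction[im],
    f_t = ts$f[it], s_t = ts$s[it], n1_t = ts$n1[it], n2_t = ts$n2[it],
    dir_t = ts$direction[it]
  )
}

#' Rename model-organism gene ids to target symbols
#'
#' Convenience for translating a test experiment against a pseudo-variance
#' table keyed by target symbols: maps the experiment's gene identifiers
#' through a resolved ortholog map, dropping genes without a partner.
#'
#' @param exp A [two_class_experiment()].
#' @param map Resolved ortholog map.
#' @param case_insensitive Match symbols case-insensitively; default
#'   `TRUE`.
#' @return A [two_class_experiment()] keyed by target symbols.
#' @export
map_to_target_symbols <- function(exp, map, case_insensitive = TRUE) {
  stopifnot(inherits(exp, "two_class_experiment"))
  key <- if (case_insensitive) tolower(rownames(exp$expr)) else
    rownames(exp$expr)
  map_key <- if (case_insensitive) tolower(map$model_symbol) else
    map$model_symbol
  idx <- match(key, map_key)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop("configuration error: no experiment genes found in the ortholog map",
         call. = FALSE)
  }
  expr <- exp$expr[keep, , drop = FALSE]
  rownames(expr) <- map$target_symbol[idx[keep]]
  two_class_experiment(expr, stats::setNames(as.character(exp$labels),
                                             colnames(expr)),
                       species = exp$species, classes = levels(exp$labels))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line as
#' `name TAB description TAB member TAB member ...`. Duplicate members
#' within a set are stored once. Lines with fewer than three fields raise a
#' parse error naming the line.
#'
#' @param path GMT file.
#' @return Named list of character vectors of member symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(stats::setNames(list(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("parse error in ", path, ": line ", short[1],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  stats::setNames(
    lapply(fields, function(x) unique(x[-(1:2)])),
    vapply(fields, `[[`, "", 1)
  )
}
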