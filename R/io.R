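# Readers and writers for the pipeline's plain-text formats: GMT gene-set
# collections, expression matrix + metadata TSVs, compound knowledgebase
# and signature-library TSVs, query JSON, result TSVs, and 16-bit TIFF
# image channels. All tabular writers accept an optional leading comment
# (used by the pipeline to stamp the run's parameter hash); readers skip
# '#' comment lines.

write_tsv_c <- function(d, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_c <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT lines are `name <tab> description <tab> member genes...`. Writing
#' then reading any collection returns it unchanged (descriptions are
#' stored in the `description` attribute).
#'
#' @param path file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file")
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT line ", short[1], ": fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  structure(sets,
            description = vapply(fields, `[`, character(1), 2L))
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0L && is.null(names(sets))) stop("sets must be named")
  if (any(lengths(sets) == 0L)) stop("empty gene set cannot be written")
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read / write an expression dataset (matrix TSV + metadata TSV)
#'
#' The matrix TSV has a first column of gene ids and one column per
#' sample; the metadata TSV has columns `sample` and `status`. Sample ids
#' must match between the files and status labels must come from
#' `vocabulary`.
#'
#' @param path_matrix,path_metadata file paths.
#' @param vocabulary allowed status labels (NULL = unrestricted).
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path_matrix, path_metadata,
                            vocabulary = c("Healthy", "NAFL", "NASH")) {
  m <- read_tsv_c(path_matrix, check.names = FALSE)
  meta <- read_tsv_c(path_metadata)
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- m[[1]]
  extra_meta <- setdiff(meta$sample, colnames(values))
  extra_mat <- setdiff(colnames(values), meta$sample)
  if (length(extra_meta) > 0L || length(extra_mat) > 0L) {
    stop("sample mismatch between matrix and metadata: ",
         paste(c(extra_meta, extra_mat), collapse = ", "))
  }
  status <- meta$status[match(colnames(values), meta$sample)]
  if (!is.null(vocabulary) && any(!status %in% vocabulary)) {
    stop("unknown status label(s): ",
         paste(unique(setdiff(status, vocabulary)), collapse = ", "))
  }
  expression_dataset(values, status)
}

#' @rdname read_expression
#' @param dataset an [expression_dataset()].
#' @param comment optional header comment.
#' @export
write_expression <- function(dataset, path_matrix, path_metadata,
                             comment = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  d <- data.frame(gene = rownames(dataset$values), dataset$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_c(d, path_matrix, comment)
  write_tsv_c(data.frame(sample = names(dataset$status),
                         status = unname(dataset$status)),
              path_metadata, comment)
  invisible(path_matrix)
}

#' Read / write a compound knowledgebase TSV
#'
#' Columns: `compound`, `targets` (semicolon-separated gene ids),
#' `tox_flag` (0/1).
#'
#' @param path file path.
#' @export
read_compound_kb <- function(path) {
  kb <- read_tsv_c(path, colClasses = c("character", "character",
                                        "integer"))
  stopifnot(all(c("compound", "targets", "tox_flag") %in% names(kb)))
  kb
}

#' @rdname read_compound_kb
#' @param kb knowledgebase data.frame.
#' @param comment optional header comment.
#' @export
write_compound_kb <- function(kb, path, comment = NULL) {
  write_tsv_c(kb, path, comment)
  invisible(path)
}

#' Read / write a signature library TSV
#'
#' One row per compound: `compound`, then the full comma-separated gene
#' ranking (first gene = rank 1 = most up-regulated).
#'
#' @param path file path.
#' @return a `signature_library`.
#' @export
read_signature_library <- function(path) {
  d <- read_tsv_c(path, colClasses = "character")
  stopifnot(all(c("compound", "ranking") %in% names(d)))
  profiles <- lapply(d$ranking, function(r) {
    genes <- strsplit(r, ",", fixed = TRUE)[[1]]
    rk <- stats::setNames(seq_along(genes), genes)
    rk[order(names(rk))]
  })
  names(profiles) <- d$compound
  universe <- if (length(profiles) > 0L) names(sort(profiles[[1]])) else
    character(0)
  structure(list(universe = universe, profiles = profiles),
            class = "signature_library")
}

#' @rdname read_signature_library
#' @param library a `signature_library`.
#' @param comment optional header comment.
#' @export
write_signature_library <- function(library, path, comment = NULL) {
  stopifnot(inherits(library, "signature_library"))
  d <- data.frame(
    compound = names(library$profiles),
    ranking = vapply(library$profiles, function(p) {
      paste(names(sort(p)), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  write_tsv_c(d, path, comment)
  invisible(path)
}

#' Read / write a query signature as JSON
#'
#' @param path file path.
#' @export
read_query_signature <- function(path) {
  q <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("up", "down") %in% names(q)))
  list(up = as.character(q$up), down = as.character(q$down))
}

#' @rdname read_query_signature
#' @param query list with `up`/`down` gene vectors.
#' @export
write_query_signature <- function(query, path) {
  jsonlite::write_json(query[c("up", "down")], path)
  invisible(path)
}

#' Write / read a two-channel image as 16-bit grayscale TIFFs
#'
#' Each channel is stored as its own 16-bit TIFF (`<stem>_nuclei.tif`,
#' `<stem>_droplets.tif`).
#'
#' @param image list with `nuclei` and `droplets` matrices in `[0, 1]`.
#' @param stem path stem.
#' @return the two file paths (invisibly for the writer).
#' @export
write_image_channels <- function(image, stem) {
  paths <- paste0(stem, c("_nuclei.tif", "_droplets.tif"))
  tiff::writeTIFF(pmin(pmax(image$nuclei, 0), 1), paths[1],
                  bits.per.sample = 16L)
  tiff::writeTIFF(pmin(pmax(image$droplets, 0), 1), paths[2],
                  bits.per.sample = 16L)
  invisible(paths)
}

#' @rdname write_image_channels
#' @export
read_image_channels <- function(stem) {
  paths <- paste0(stem, c("_nuclei.tif", "_droplets.tif"))
  list(nuclei = tiff::readTIFF(paths[1]),
       droplets = tiff::readTIFF(paths[2]))
}

#' Write a gene-statistics table TSV
#'
#' Fixed column order: gene, log2FC, s2, df, s2_post, t_mod, p, p_adj,
#' de_class (extra columns appended).
#'
#' @param stats gene-statistics data.frame.
#' @param path file path.
#' @param comment optional header comment.
#' @export
write_gene_stats <- function(stats, path, comment = NULL) {
  first <- c("gene", "log2FC", "s2", "df", "s2_post", "t_mod", "p",
             "p_adj", "de_class")
  stats <- stats[, c(first, setdiff(names(stats), first)), drop = FALSE]
  write_tsv_c(stats, path, comment)
  invisible(path)
}

#' @rdname write_gene_stats
#' @export
read_gene_stats <- function(path) read_tsv_c(path)
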