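#' Construct a metabolome matrix
#'
#' The central data container of the pipeline: a non-negative intensity
#' matrix (samples in rows, metabolites in columns) together with the sample
#' metadata (variety, hours after imbibition, replicate) and metabolite
#' annotations (name, compound class, optional module tag). Intensities are
#' stored exactly as given -- no transformation is applied at I/O time; any
#' transform is an explicit option of the downstream operation. `NA` cells
#' are allowed and every statistical operation documents its own missing
#' policy.
#'
#' @param values numeric matrix, samples x metabolites, all present values
#'   `>= 0`. `NA` marks missing cells.
#' @param samples data frame with columns `sample_id`, `variety`,
#'   `timepoint_hai` (hours after imbibition, integer `>= 0`) and
#'   `replicate` (integer `>= 1`); one row per row of `values`. The
#'   `(variety, timepoint_hai, replicate)` triple must be unique.
#' @param metabolites data frame with column `metabolite_id` (unique) and
#'   optional `name`, `compound_class`, `module_tag`; one row per column of
#'   `values`. Missing annotation columns are filled with defaults
#'   (`name = metabolite_id`, `compound_class = "others"`,
#'   `module_tag = "none"`).
#' @return an object of class `metabolome_matrix`: a list with elements
#'   `values`, `samples`, `metabolites`.
#' @examples
#' vals <- matrix(c(1, 2, 3, 4), 2, 2,
#'                dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' smp <- data.frame(sample_id = c("s1", "s2"), variety = "A",
#'                   timepoint_hai = 0, replicate = 1:2)
#' met <- data.frame(metabolite_id = c("m1", "m2"))
#' metabolome_matrix(vals, smp, met)
#' @export
metabolome_matrix <- function(values, samples, metabolites) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples)
  metabolites <- as.data.frame(metabolites)

  need_s <- c("sample_id", "variety", "timepoint_hai", "replicate")
  miss <- setdiff(need_s, names(samples))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!("metabolite_id" %in% names(metabolites)))
    stop("metabolite annotation lacks column 'metabolite_id'")
  if (is.null(metabolites$name)) metabolites$name <- metabolites$metabolite_id
  if (is.null(metabolites$compound_class)) metabolites$compound_class <- "others"
  if (is.null(metabolites$module_tag)) metabolites$module_tag <- "none"

  if (nrow(samples) != nrow(values))
    stop("values has ", nrow(values), " rows but sample metadata has ",
         nrow(samples), " rows")
  if (nrow(metabolites) != ncol(values))
    stop("values has ", ncol(values), " columns but metabolite annotation has ",
         nrow(metabolites), " rows")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  if (anyDuplicated(metabolites$metabolite_id))
    stop("duplicate metabolite_id: ",
         metabolites$metabolite_id[duplicated(metabolites$metabolite_id)][1])
  trip <- paste(samples$variety, samples$timepoint_hai, samples$replicate)
  if (anyDuplicated(trip))
    stop("duplicate (variety, timepoint_hai, replicate) triple: ",
         trip[duplicated(trip)][1])
  if (any(samples$timepoint_hai < 0))
    stop("timepoint_hai must be >= 0")
  if (any(samples$replicate < 1))
    stop("replicate must be >= 1")

  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative intensity at sample '", samples$sample_id[bad[1, 1]],
         "', metabolite '", metabolites$metabolite_id[bad[1, 2]], "': ",
         values[bad[1, 1], bad[1, 2]])

  rownames(values) <- samples$sample_id
  colnames(values) <- metabolites$metabolite_id
  structure(list(values = values,
                 samples = tibble::as_tibble(samples),
                 metabolites = tibble::as_tibble(metabolites)),
            class = "metabolome_matrix")
}

#' @export
print.metabolome_matrix <- function(x, ...) {
  cat("<metabolome_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values), " metabolites\n", sep = "")
  cat("  varieties: ", paste(unique(x$samples$variety), collapse = ", "),
      "\n", sep = "")
  cat("  timepoints (HAI): ",
      paste(sort(unique(x$samples$timepoint_hai)), collapse = ", "),
      "\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolome_matrix <- function(x) dim(x$values)

# subset a metabolome_matrix by sample index, keeping metadata in step
subset_samples <- function(mat, keep) {
  metabolome_matrix(mat$values[keep, , drop = FALSE],
                    mat$samples[keep, , drop = FALSE],
                    mat$metabolites)
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) >
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

read_table_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delim %||% detect_delim(path)
  read.csv(path, sep = delim, check.names = FALSE,
           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a metabolome intensity table
#'
#' Reads a CSV/TSV intensity table in either layout:
#' \describe{
#'   \item{wide}{metadata columns `sample_id`, `variety`, `timepoint_hai`,
#'     `replicate`, followed by one numeric column per metabolite.}
#'   \item{long}{columns `sample_id`, `variety`, `timepoint_hai`,
#'     `replicate`, `metabolite_id`, `intensity`; one row per cell.
#'     Duplicate (sample, metabolite) pairs are an error; absent pairs
#'     become missing cells.}
#' }
#' Empty cells become `NA`. Negative intensities are rejected with the
#' offending sample/metabolite named. The delimiter is auto-detected
#' between comma and tab unless given.
#'
#' @param path file path.
#' @param layout `"wide"` or `"long"`.
#' @param annotations optional metabolite annotation data frame (see
#'   [metabolome_matrix()]); by default minimal annotations are derived
#'   from the column names / `metabolite_id` values.
#' @param delim optional explicit field delimiter.
#' @return a [metabolome_matrix()].
#' @seealso [write_metabolome()], [read_annotations()]
#' @export
read_metabolome <- function(path, layout = c("wide", "long"),
                            annotations = NULL, delim = NULL) {
  layout <- match.arg(layout)
  tab <- read_table_auto(path, delim)
  meta_cols <- c("sample_id", "variety", "timepoint_hai", "replicate")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))

  if (layout == "wide") {
    met_ids <- setdiff(names(tab), meta_cols)
    if (!length(met_ids)) stop("no metabolite columns found in ", path)
    vals <- as.matrix(tab[met_ids])
    storage.mode(vals) <- "double"
    samples <- tab[meta_cols]
  } else {
    if (!all(c("metabolite_id", "intensity") %in% names(tab)))
      stop("malformed header in ", path,
           ": long layout needs columns metabolite_id, intensity")
    key <- paste(tab$sample_id, tab$metabolite_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- tab[duplicated(key), ][1, ]
      stop("duplicate cell for sample '", d$sample_id, "', metabolite '",
           d$metabolite_id, "'")
    }
    sids <- unique(tab$sample_id)
    met_ids <- unique(tab$metabolite_id)
    vals <- matrix(NA_real_, length(sids), length(met_ids),
                   dimnames = list(sids, met_ids))
    vals[cbind(match(tab$sample_id, sids),
               match(tab$metabolite_id, met_ids))] <- tab$intensity
    samples <- unique(tab[meta_cols])
    samples <- samples[match(sids, samples$sample_id), ]
  }
  if (is.null(annotations))
    annotations <- data.frame(metabolite_id = met_ids,
                              stringsAsFactors = FALSE)
  ann <- annotations[match(met_ids, annotations$metabolite_id), , drop = FALSE]
  if (anyNA(ann$metabolite_id))
    stop("annotation table lacks metabolite(s): ",
         paste(head(met_ids[is.na(ann$metabolite_id)], 3), collapse = ", "))
  metabolome_matrix(vals, samples, ann)
}

#' Write a metabolome matrix to CSV
#'
#' Inverse of [read_metabolome()]; `read(write(x))` reproduces `x` for both
#' layouts (decimal text round-trip at full double precision).
#'
#' @param mat a [metabolome_matrix()].
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_metabolome <- function(mat, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  smp <- as.data.frame(mat$samples[c("sample_id", "variety",
                                     "timepoint_hai", "replicate")])
  if (layout == "wide") {
    out <- cbind(smp, as.data.frame(mat$values, check.names = FALSE))
  } else {
    idx <- which(!is.na(mat$values) | TRUE, arr.ind = TRUE)  # all cells
    keep <- !is.na(mat$values[idx])
    idx <- idx[keep, , drop = FALSE]
    out <- cbind(smp[idx[, 1], , drop = FALSE],
                 data.frame(metabolite_id = colnames(mat$values)[idx[, 2]],
                            intensity = mat$values[idx]))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a metabolite annotation table
#'
#' Columns: `metabolite_id` (required), `name`, `compound_class`,
#' `module_tag`. Compound classes are an open vocabulary (e.g. lipids,
#' flavonoids, amino acids and derivatives, polyamines, organic acids,
#' terpenes, nucleotides and derivatives, phytohormones, sugars, vitamins
#' and derivatives, others).
#'
#' @param path file path (CSV/TSV, delimiter auto-detected).
#' @param delim optional explicit delimiter.
#' @return a tibble.
#' @export
read_annotations <- function(path, delim = NULL) {
  tab <- read_table_auto(path, delim)
  if (!("metabolite_id" %in% names(tab)))
    stop("annotation table lacks column 'metabolite_id'")
  if (anyDuplicated(tab$metabolite_id))
    stop("duplicate metabolite_id in annotation table")
  tibble::as_tibble(tab)
}

#' Read a germination phenotype table
#'
#' Columns: `variety`, `timepoint_hai`, `germination_fraction` (in
#' `[0, 1]`); optional `replicate`, `fresh_weight`, `dry_weight` (grams,
#' positive) and `treatment`. Within each variety (x treatment x replicate)
#' series a decreasing germination fraction is a warning, not an error, as
#' counting noise in real assays can produce small dips. `fresh_weight <
#' dry_weight` likewise warns.
#'
#' @param path file path (CSV/TSV, delimiter auto-detected).
#' @param delim optional explicit delimiter.
#' @return a tibble of class `germination_phenotype`.
#' @export
read_phenotype <- function(path, delim = NULL) {
  tab <- read_table_auto(path, delim)
  validate_phenotype(tab)
}

#' Validate a germination phenotype table
#'
#' @param tab data frame; see [read_phenotype()] for the schema.
#' @param check_monotone warn when a germination series decreases over
#'   time (default `TRUE`).
#' @return the validated tibble (invisibly classed `germination_phenotype`).
#' @export
validate_phenotype <- function(tab, check_monotone = TRUE) {
  need <- c("variety", "timepoint_hai", "germination_fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  g <- tab$germination_fraction
  if (any(g < 0 | g > 1, na.rm = TRUE))
    stop("germination_fraction outside [0, 1]")
  if (all(c("fresh_weight", "dry_weight") %in% names(tab))) {
    both <- !is.na(tab$fresh_weight) & !is.na(tab$dry_weight)
    if (any(tab$dry_weight[both] <= 0))
      stop("dry_weight must be positive")
    if (any(tab$fresh_weight[both] < tab$dry_weight[both]))
      warning("fresh_weight < dry_weight in ",
              sum(tab$fresh_weight[both] < tab$dry_weight[both]), " row(s)")
  }
  if (!check_monotone) {
    out <- tibble::as_tibble(tab)
    class(out) <- c("germination_phenotype", class(out))
    return(out)
  }
  grp <- paste(tab$variety,
               if (is.null(tab$treatment)) "" else tab$treatment,
               if (is.null(tab$replicate)) "" else tab$replicate)
  for (g_id in unique(grp)) {
    rows <- tab[grp == g_id, ]
    rows <- rows[order(rows$timepoint_hai), ]
    if (is.unsorted(rows$germination_fraction, strictly = FALSE) &&
        any(diff(rows$germination_fraction) < 0)) {
      warning("germination_fraction decreases over time for ",
              rows$variety[1])
      break
    }
  }
  out <- tibble::as_tibble(tab)
  class(out) <- c("germination_phenotype", class(out))
  out
}

#' Export a metabolite-trait correlation network
#'
#' Writes the correlation edges produced by [cor_screen()] as generic graph
#' files loadable by Cytoscape-like tools: a CSV edge table
#' (`<prefix>_edges.csv`: source metabolite, target trait node per variety,
#' weight = r, sign), a CSV node table (`<prefix>_nodes.csv`: node id, type,
#' compound class), and optional SIF and GraphML mirrors.
#'
#' @param edges tibble of correlation edges (columns `metabolite_id`,
#'   `variety`, `r`; rows with `passes == FALSE` are dropped if the column
#'   is present). May be empty.
#' @param node_annotations optional metabolite annotation table
#'   (`metabolite_id`, `compound_class`).
#' @param out_prefix path prefix for the emitted files.
#' @param formats subset of `c("csv", "sif", "graphml")`.
#' @return named character vector of the files written, invisibly.
#' @export
write_network <- function(edges, node_annotations = NULL, out_prefix,
                          formats = c("csv", "sif", "graphml")) {
  formats <- match.arg(formats, several.ok = TRUE)
  edges <- as.data.frame(edges)
  if (!is.null(edges$passes)) edges <- edges[which(edges$passes), , drop = FALSE]
  et <- data.frame(
    source = edges$metabolite_id %||% character(),
    target = if (nrow(edges)) paste0("germination_rate_", edges$variety)
             else character(),
    weight = edges$r %||% numeric(),
    sign = if (nrow(edges)) ifelse(edges$r >= 0, "positive", "negative")
           else character(),
    stringsAsFactors = FALSE)

  nodes <- unique(c(et$source, et$target))
  nt <- data.frame(node = nodes,
                   type = ifelse(grepl("^germination_rate_", nodes),
                                 "trait", "metabolite"),
                   stringsAsFactors = FALSE)
  if (!is.null(node_annotations)) {
    ann <- as.data.frame(node_annotations)
    nt$compound_class <-
      ann$compound_class[match(nt$node, ann$metabolite_id)]
  }

  written <- character()
  if ("csv" %in% formats) {
    fe <- paste0(out_prefix, "_edges.csv")
    fn <- paste0(out_prefix, "_nodes.csv")
    write.csv(et, fe, row.names = FALSE, fileEncoding = "UTF-8")
    write.csv(nt, fn, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, edges_csv = fe, nodes_csv = fn)
  }
  if ("sif" %in% formats) {
    fs <- paste0(out_prefix, ".sif")
    writeLines(if (nrow(et))
                 paste(et$source, et$sign, et$target, sep = "\t")
               else character(), fs)
    written <- c(written, sif = fs)
  }
  if ("graphml" %in% formats && nrow(et)) {
    fg <- paste0(out_prefix, ".graphml")
    g <- igraph::graph_from_data_frame(et, directed = FALSE, vertices = nt)
    igraph::write_graph(g, fg, format = "graphml")
    written <- c(written, graphml = fg)
  }
  invisible(written)
}

#' Read back a correlation-network edge table
#'
#' Counterpart of [write_network()]'s CSV output, used for lossless
#' round-trip checks.
#'
#' @param out_prefix the prefix passed to [write_network()].
#' @return tibble with columns `source`, `target`, `weight`, `sign`.
#' @export
read_network_edges <- function(out_prefix) {
  tibble::as_tibble(read.csv(paste0(out_prefix, "_edges.csv"),
                             stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
}
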