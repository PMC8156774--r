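#' Read an off-target table
#'
#' Reads a delimited table of (sgRNA sequence, target DNA sequence, binary
#' label) records, the curated format used by sequence-only off-target
#' predictors: each sequence is 23 nt (20-nt spacer followed by a 3-nt PAM)
#' and the label is 1 for a confirmed off-target site (OT) and 0 for a
#' candidate site with no observed cleavage (NOT).
#'
#' The delimiter is sniffed from the first line (comma or tab) unless given.
#' Columns are resolved by header name when a header row matching `col_map`
#' names is present, otherwise by position (sgrna, target, label = columns
#' 1, 2, 3).
#'
#' @param path Path to a CSV or TSV file.
#' @param delim Field delimiter; `NULL` (default) sniffs `","` vs `"\t"`.
#' @param col_map Named character vector mapping the roles `sgrna`, `target`,
#'   `label` (and optionally `cell_type`) to column names in the file header.
#' @return A tibble with columns `sgrna`, `target`, `label` (integer 0/1) and,
#'   when mapped, `cell_type`, one row per data row in file order.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sgrna,target,label",
#'              "GGGTGGGGGGAGTTTGCTCCTGG,GGATGGAGGGAGTTTGCTCCTGG,1"), tf)
#' read_offtarget_table(tf)
#' @export
read_offtarget_table <- function(path, delim = NULL,
                                 col_map = c(sgrna = "sgrna", target = "target",
                                             label = "label")) {
  if (!file.exists(path)) {
    abort(paste0("off-target table not found: ", path))
  }
  first <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0L && ncol(tab) == 0L) {
    return(tibble(sgrna = character(), target = character(), label = integer()))
  }

  required <- c("sgrna", "target", "label")
  have_header <- all(col_map[required] %in% names(tab))
  if (have_header) {
    out <- tibble(
      sgrna = tab[[col_map[["sgrna"]]]],
      target = tab[[col_map[["target"]]]],
      label = tab[[col_map[["label"]]]]
    )
    if ("cell_type" %in% names(col_map) && col_map[["cell_type"]] %in% names(tab)) {
      out$cell_type <- tab[[col_map[["cell_type"]]]]
    }
  } else {
    if (ncol(tab) < 3L) {
      abort(paste0("cannot resolve sgrna/target/label columns in ", path,
                   ": no matching header and fewer than 3 columns"))
    }
    # Headerless file: read_delim consumed row 1 as names; reread without it.
    tab <- readr::read_delim(path, delim = delim, col_names = FALSE,
                             col_types = readr::cols(.default = readr::col_character()),
                             show_col_types = FALSE, progress = FALSE)
    out <- tibble(sgrna = tab[[1]], target = tab[[2]], label = tab[[3]])
  }

  bad <- which(!out$label %in% c("0", "1"))
  if (length(bad) > 0L) {
    abort(paste0("non-binary label value ", dQuote(out$label[bad[1]]),
                 " on row ", bad[1]))
  }
  out$label <- as.integer(out$label)
  out
}

#' Check off-target records against the format contract
#'
#' Enumerates every violation of the record invariants: no missing fields,
#' both sequences exactly 23 nt, characters drawn only from uppercase
#' A/C/G/T (case-sensitive), label in {0, 1}.
#'
#' @param records A tibble with columns `sgrna`, `target`, `label`.
#' @return A tibble of violations with columns `row`, `field`, `problem`;
#'   zero rows when all records pass.
#' @seealso [validate_records()]
#' @export
check_records <- function(records) {
  stopifnot(all(c("sgrna", "target", "label") %in% names(records)))
  report <- list()
  add <- function(rows, field, problem) {
    if (length(rows) > 0L) {
      report[[length(report) + 1L]] <<- tibble(row = as.integer(rows),
                                              field = field, problem = problem)
    }
  }
  for (field in c("sgrna", "target")) {
    x <- records[[field]]
    add(which(is.na(x)), field, "null field")
    ok <- !is.na(x)
    add(which(ok & nchar(x) != SEQ_LEN), field, "length != 23")
    add(which(ok & nchar(x) == SEQ_LEN & !grepl("^[ACGT]+$", x)),
        field, "invalid character")
  }
  add(which(is.na(records$label)), "label", "null field")
  add(which(!is.na(records$label) & !records$label %in% c(0L, 1L)),
      "label", "label not in {0,1}")
  if (length(report) == 0L) {
    return(tibble(row = integer(), field = character(), problem = character()))
  }
  arrange(bind_rows(report), .data$row, .data$field)
}

#' Validate off-target records
#'
#' Applies the case-sensitive sequence validation used before graph
#' construction. In strict mode (the default) the first violation aborts with
#' its row index; in lenient mode offending rows are dropped and the full
#' violation report is attached as the `"report"` attribute.
#'
#' @inheritParams check_records
#' @param mode `"strict"` (abort on violation) or `"lenient"` (drop and report).
#' @return The validated tibble; in lenient mode with `attr(, "report")`.
#' @export
validate_records <- function(records, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  report <- check_records(records)
  if (nrow(report) == 0L) {
    attr(records, "report") <- report
    return(records)
  }
  if (mode == "strict") {
    v <- report[1L, ]
    abort(paste0("invalid off-target record on row ", v$row, " (", v$field,
                 "): ", v$problem,
                 if (nrow(report) > 1L) paste0(" [", nrow(report) - 1L,
                                               " further violation(s)]") else ""))
  }
  keep <- setdiff(seq_len(nrow(records)), unique(report$row))
  out <- records[keep, , drop = FALSE]
  attr(out, "report") <- report
  inform(paste0("dropped ", length(unique(report$row)),
                " invalid record(s); see attr(x, \"report\")"))
  out
}

#' Encode sequences as integer node IDs
#'
#' Deduplicates the union of sgRNA and target sequences and assigns node IDs
#' `0..N-1` by lexicographic (byte) order over uppercase ACGT, so the mapping
#' is a bijection that does not depend on row order.
#'
#' @inheritParams check_records
#' @return A tibble with columns `node_id` (integer, 0-based) and `sequence`,
#'   sorted by `node_id`.
#' @export
encode_sequence_ids <- function(records) {
  seqs <- sort(unique(c(records$sgrna, records$target)), method = "radix")
  tibble(node_id = seq_along(seqs) - 1L, sequence = seqs)
}

# ---- artifact serialization -------------------------------------------------

#' Write / read a sequence graph as plain text
#'
#' The edge list is a two-column TSV of 0-based node IDs; the node table is a
#' TSV of `node_id`, `sequence`, `role`. Together they round-trip the graph
#' exactly.
#'
#' @param graph An [ot_graph][build_graph()] object.
#' @param edge_path,node_path Output TSV paths.
#' @return `write_graph()` returns `graph` invisibly; `read_graph()` returns
#'   an `ot_graph`.
#' @export
write_graph <- function(graph, edge_path, node_path) {
  stopifnot(inherits(graph, "ot_graph"))
  readr::write_tsv(graph$edges, edge_path, progress = FALSE)
  readr::write_tsv(graph$nodes, node_path, progress = FALSE)
  invisible(graph)
}

#' @rdname write_graph
#' @export
read_graph <- function(edge_path, node_path) {
  edges <- readr::read_tsv(edge_path, col_types = "ii", progress = FALSE)
  nodes <- readr::read_tsv(node_path, col_types = "icc", progress = FALSE)
  new_ot_graph(nodes, edges)
}

#' Write / read a node feature matrix
#'
#' TSV with a `# scheme: <name>` comment line, a header of `node_id` plus
#' feature column names, and one row per node.
#'
#' @param features A feature tibble from [kmer_features()] or
#'   [positional_features()].
#' @param path Output TSV path.
#' @return `write_features()` returns `features` invisibly; `read_features()`
#'   the reconstructed feature tibble (errors if the scheme header is absent).
#' @export
write_features <- function(features, path) {
  scheme <- attr(features, "scheme")
  stopifnot(!is.null(scheme))
  writeLines(paste0("# scheme: ", scheme), path)
  readr::write_tsv(features, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# scheme: ", first)) {
    abort(paste0("feature file ", path, " lacks a '# scheme:' header"))
  }
  scheme <- sub("^# scheme: ", "", first)
  out <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    node_id = readr::col_integer(), .default = readr::col_double()
  ), progress = FALSE)
  attr(out, "scheme") <- scheme
  out
}

#' Write / read run metrics as JSON
#'
#' Stores auROC and accuracy values, per-epoch loss history, seed and the
#' configuration of a run in one JSON document.
#'
#' @param metrics A named list (numbers, vectors, nested lists).
#' @param path Output JSON path.
#' @return `write_metrics()` returns `metrics` invisibly; `read_metrics()`
#'   the reconstructed list.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(metrics)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read model parameters
#'
#' Serializes GCN layer weights and the dense head to JSON, encoding doubles
#' as 17-significant-digit decimal strings, which round-trip IEEE doubles
#' exactly, so reloaded parameters reproduce forward outputs bit for bit.
#'
#' @param params A parameter list from [init_link_params()] or a fitted model's
#'   `$params`.
#' @param path Output JSON path.
#' @return `write_params()` returns `params` invisibly; `read_params()` the
#'   reconstructed parameter list with matrix shapes restored.
#' @export
write_params <- function(params, path) {
  enc <- function(x) sprintf("%.17g", as.numeric(x))
  ser <- list(
    gcn = map(params$gcn, function(W) {
      list(dim = dim(W), values = enc(W))
    }),
    head = list(w = enc(params$head$w), b = enc(params$head$b))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE)
  invisible(params)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  gcn <- map(ser$gcn, function(layer) {
    matrix(as.numeric(layer$values), nrow = layer$dim[1], ncol = layer$dim[2])
  })
  list(gcn = unname(gcn),
       head = list(w = as.numeric(ser$head$w), b = as.numeric(ser$head$b)))
}
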