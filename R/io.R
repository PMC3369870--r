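#' Machine JSON serialization
#'
#' Serializes a machine to JSON with fields `alphabet`, `states`,
#' `transitions` (array of `{from, symbol, to, p}`, sorted by `(from,
#' symbol)`) and `notes`.  Round trips are exact and, because of the
#' canonical key/row ordering, byte-stable.
#'
#' @param m a [machine].
#' @return JSON string.
#' @export
machine_to_json <- function(m) {
  obj <- list(alphabet = m$alphabet, states = m$states,
              transitions = transitions(m), notes = m$notes)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"))
}

#' @rdname machine_to_json
#' @param json JSON string produced by [machine_to_json()].
#' @export
machine_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  machine(obj$transitions, states = obj$states, alphabet = obj$alphabet,
          notes = obj$notes %||% "")
}

#' @rdname machine_to_json
#' @param path file path.
#' @export
write_machine_json <- function(m, path) {
  writeLines(machine_to_json(m), path)
  invisible(path)
}

#' @rdname machine_to_json
#' @export
read_machine_json <- function(path) {
  machine_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' DOT export of a machine
#'
#' Graphviz DOT source with one node per state and edges labeled
#' `"symbol | p"`.
#'
#' @param m a [machine].
#' @param name graph name.
#' @return character vector of DOT lines.
#' @export
machine_to_dot <- function(m, name = "machine") {
  tr <- transitions(m)
  c(sprintf("digraph %s {", name),
    "  rankdir=LR;",
    sprintf('  "%s" [shape=circle];', m$states),
    sprintf('  "%s" -> "%s" [label="%s | %.6g"];',
            tr$from, tr$to, tr$symbol, tr$p),
    "}")
}

#' Dump populations as FASTA-like plain text
#'
#' One record per generation (`>gen_<t>` followed by the allele string), for
#' interoperability with sequence tooling.
#'
#' @param populations list (or single vector) of allele character vectors.
#' @param path output file.
#' @export
write_population_fasta <- function(populations, path) {
  if (!is.list(populations)) populations <- list(populations)
  lines <- unlist(lapply(seq_along(populations), function(i) {
    c(sprintf(">gen_%d", i - 1), paste(populations[[i]], collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Flat key-value YAML mirroring the CLI flags (see
#' `system.file("extdata", "csv-columns.tsv", package = "structdrift")` for
#' output schemas).
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# per-realization trajectory CSV (generation, h_mu, C_mu, p_tracked,
# signature, event)
write_trajectory_csv <- function(traj, path) {
  if (is.null(traj$records)) stop("trajectory was run with record = 'minimal'")
  utils::write.csv(traj$records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
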