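# Classed error conditions so callers (and the CLI) can map failures to
# categories: format, topology, cell, selection, domain, pbc_range, metadata.

abort_trrdf <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "trrdf_error"), call = call))
}

format_error    <- function(msg) abort_trrdf(msg, "trrdf_format_error")
topology_error  <- function(msg) abort_trrdf(msg, "trrdf_topology_error")
cell_error      <- function(msg) abort_trrdf(msg, "trrdf_cell_error")
selection_error <- function(msg) abort_trrdf(msg, "trrdf_selection_error")
domain_error    <- function(msg) abort_trrdf(msg, "trrdf_domain_error")
pbc_range_error <- function(msg) abort_trrdf(msg, "trrdf_pbc_range_error")
metadata_error  <- function(msg) abort_trrdf(msg, "trrdf_metadata_error")
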