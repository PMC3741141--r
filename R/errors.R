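# Classed conditions so callers (and the CLI) can map failures to a
# category: format, value, key, duplicate, capacity.

abort_pheno <- function(subclass, msg) {
  stop(structure(
    class = c(subclass, "phenoarc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_format    <- function(msg) abort_pheno("phenoarc_format_error", msg)
abort_value     <- function(msg) abort_pheno("phenoarc_value_error", msg)
abort_key       <- function(msg) abort_pheno("phenoarc_key_error", msg)
abort_duplicate <- function(msg) abort_pheno("phenoarc_duplicate_error", msg)
abort_capacity  <- function(msg) abort_pheno("phenoarc_capacity_error", msg)
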