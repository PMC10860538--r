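# Run code with a temporarily-seeded RNG, restoring global state afterwards.
# All stochastic entry points take an explicit seed and route through here so
# nothing in the package perturbs (or depends on) the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (keeps every derived
# seed inside the 32-bit signed-integer range).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- rlang::`%||%`

# signature helpers -----------------------------------------------------
# A clone signature is a named character vector: variant_id -> "HET"/"HOM".
# Absent variant = WT. Zygosity is ordered WT < HET < HOM.

ZYG_RANK <- c(WT = 0L, HET = 1L, HOM = 2L)

signature_string <- function(sig) {
  if (length(sig) == 0) return("WT")
  ord <- order(names(sig))
  paste(names(sig)[ord], unname(sig)[ord], sep = ":", collapse = ";")
}

parse_signature <- function(s) {
  if (identical(s, "WT") || is.na(s) || s == "") {
    return(stats::setNames(character(0), character(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  # variant ids may themselves contain ':'; zygosity is the last field
  zyg <- vapply(parts, function(p) p[length(p)], character(1))
  var <- vapply(parts, function(p) paste(p[-length(p)], collapse = ":"),
                character(1))
  stats::setNames(zyg, var)
}

# TRUE if `anc` is an ancestor-or-equal signature of `des`: every mutated
# variant of anc appears in des with zygosity >= anc's (HET may progress to
# HOM, never the reverse).
sig_ancestor_of <- function(anc, des) {
  if (length(anc) == 0) return(TRUE)
  idx <- match(names(anc), names(des))
  if (anyNA(idx)) return(FALSE)
  all(ZYG_RANK[des[idx]] >= ZYG_RANK[anc])
}

sig_n_mutations <- function(sig) length(sig)
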