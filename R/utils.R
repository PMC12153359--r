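# Internal helpers shared across modules.

# Item strings are "<virus_id>=T" or "<virus_id>=F". Virus ids may contain
# any character except "=" and ";" (";" separates items of a LHS).
.item <- function(virus, state) {
  if (length(virus) == 0L) {
    return(character(0))
  }
  paste0(virus, "=", ifelse(state, "T", "F"))
}

.item_virus <- function(items) sub("=[TF]$", "", items)

.item_state <- function(items) {
  st <- substring(items, nchar(items))
  if (!all(st %in% c("T", "F"))) {
    stop("malformed item(s): ", paste(items[!st %in% c("T", "F")], collapse = ", "))
  }
  st == "T"
}

.split_items <- function(lhs) strsplit(lhs, ";", fixed = TRUE)

# Canonical item order: lexicographic by virus id (C locale for stability),
# presence before absence for the same virus (cannot co-occur in a valid set,
# but keeps ordering total).
.sort_items <- function(items) {
  ord <- order(.item_virus(items), !.item_state(items), method = "radix")
  items[ord]
}

.join_items <- function(items) paste(.sort_items(items), collapse = ";")

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child seeds from a master seed; kept inside 32-bit range.
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
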