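# Block labels: a human chromosome ("1".."22", "X"), an optional arm hint
# (p/q), an optional sub-block letter distinguishing multiple blocks of the
# same human chromosome, and an optional trailing "?" marking an uncertain
# segment. Examples: "8", "8a", "16q", "4?", "2p".

HSA_LEVELS <- c(as.character(1:22), "X", "Y")

#' Parse block label tokens
#'
#' Splits painting-map segment tokens such as `"8a"`, `"16q"` or `"21?"` into
#' their components: human chromosome, arm hint, sub-block letter and
#' uncertainty flag.
#'
#' @param x Character vector of block label tokens.
#' @return A tibble with columns `hsa`, `arm_hint`, `sub_block`, `uncertain`.
#' @examples
#' parse_block_label(c("8a", "16q", "21?"))
#' @export
parse_block_label <- function(x) {
  m <- stringr::str_match(x, "^(2[0-2]|1[0-9]|[1-9]|X|Y)([pq])?([a-f])?(\\?)?$")
  bad <- is.na(m[, 1]) & !is.na(x)
  if (any(bad)) {
    abort(paste0("unknown block label(s): ", paste(unique(x[bad]), collapse = ", ")))
  }
  tibble(
    hsa = m[, 2],
    arm_hint = m[, 3],
    sub_block = m[, 4],
    uncertain = !is.na(m[, 5])
  )
}

#' Format block labels from components
#'
#' Inverse of [parse_block_label()].
#'
#' @param hsa,arm_hint,sub_block,uncertain Label components.
#' @return Character vector of tokens.
#' @export
format_block_label <- function(hsa, arm_hint = NA, sub_block = NA, uncertain = FALSE) {
  paste0(
    hsa,
    ifelse(is.na(arm_hint), "", arm_hint),
    ifelse(is.na(sub_block), "", sub_block),
    ifelse(uncertain, "?", "")
  )
}

# Canonical member order for association identities: numeric human chromosome
# order with X last, so the printed "12/22/16" becomes "12/16/22".
hsa_rank <- function(hsa) {
  r <- suppressWarnings(as.integer(hsa))
  r[hsa == "X"] <- 23L
  r[hsa == "Y"] <- 24L
  r
}

#' Canonical association identity
#'
#' An association is an unordered set of two or more human chromosomes whose
#' segments share one target chromosome. Its canonical identity sorts the
#' members in numeric order, e.g. `association_id(c("22", "12", "16"))` is
#' `"12/16/22"`.
#'
#' @param members Character vector of human chromosome labels.
#' @return A single string identity.
#' @export
association_id <- function(members) {
  members <- unique(members)
  if (length(members) < 2) {
    abort("an association needs at least two distinct human chromosomes")
  }
  paste(members[order(hsa_rank(members))], collapse = "/")
}

association_members <- function(id) stringr::str_split_1(id, "/")
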