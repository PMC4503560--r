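# Junction and boundary probes.
#
# Reads are only counted where they cross an IES end, so every IES gets
# three probes of identical width 2k+2 (k = flank width in bases):
#   minus_probe      k MAC bases | junction TA | k MAC bases
#   plus_left_probe  k MAC bases | first k+2 IES bases
#   plus_right_probe last k+2 IES bases | k MAC bases
# A read containing a plus probe supports the unexcised (IES+) form; a
# read containing the minus probe supports the excised (IES-) junction.

#' Build junction/boundary probes for IESs
#'
#' Extracts, for each annotated IES, the excised-junction probe from the
#' MAC reference and the two boundary probes from the MAC+IES reference
#' (all of width `2k + 2`).
#'
#' IESs whose flanks do not fit on the scaffold (within `k` bases of an
#' end) cannot be probed; IESs whose three probes are not three distinct
#' strings at this `k` would make read classification ambiguous by
#' construction. Both cases are flagged `countable = FALSE` with a
#' `reason`, and either raise an error or a warning depending on
#' `on_uncountable`.
#'
#' @param mac MAC genome.
#' @param mac_plus_ies MAC+IES genome from [insert_ies()].
#' @param annotations IES annotation tibble.
#' @param k Flank width in bases (>= 1).
#' @param on_uncountable `"error"` (default) or `"drop"`; with `"drop"`
#'   uncountable IESs are kept in the table, flagged, and a warning lists
#'   them.
#' @return A tibble with columns `ies_id`, `minus_probe`,
#'   `plus_left_probe`, `plus_right_probe`, `k`, `countable`, `reason`.
#' @export
make_probes <- function(mac, mac_plus_ies, annotations, k = 5L,
                        on_uncountable = c("error", "drop")) {
  on_uncountable <- match.arg(on_uncountable)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    abort("`k` must be a single integer >= 1")
  }
  k <- as.integer(k)
  mac <- as_genome(mac)
  mac_plus_ies <- as_genome(mac_plus_ies)
  coords <- ies_coordinates(validate_ies_annotations(annotations, mac))
  if (nrow(coords) == 0L) {
    return(tibble(ies_id = character(), minus_probe = character(),
                  plus_left_probe = character(), plus_right_probe = character(),
                  k = integer(), countable = logical(), reason = character()))
  }
  mac_chr <- as.character(mac)
  gl_chr <- as.character(mac_plus_ies)
  mac_w <- setNames(nchar(mac_chr), names(mac_chr))
  gl_w <- setNames(nchar(gl_chr), names(gl_chr))

  fits <- coords$junction_pos - k >= 1L &
    coords$junction_pos + 1L + k <= mac_w[coords$scaffold] &
    coords$start - k >= 1L & coords$end + k <= gl_w[coords$scaffold]

  minus <- ifelse(fits, substr(mac_chr[coords$scaffold],
                               coords$junction_pos - k,
                               coords$junction_pos + 1L + k), NA_character_)
  plus_left <- ifelse(fits, substr(gl_chr[coords$scaffold],
                                   coords$start - k, coords$start + k + 1L),
                      NA_character_)
  plus_right <- ifelse(fits, substr(gl_chr[coords$scaffold],
                                    coords$end - k - 1L, coords$end + k),
                       NA_character_)

  degenerate <- fits & (minus == plus_left | minus == plus_right |
                          plus_left == plus_right)
  probes <- tibble(
    ies_id = coords$ies_id,
    minus_probe = minus,
    plus_left_probe = plus_left,
    plus_right_probe = plus_right,
    k = k,
    countable = fits & !degenerate,
    reason = case_when(
      !fits ~ "probe_unavailable_near_scaffold_end",
      degenerate ~ sprintf("degenerate_probes_at_k_%d", k),
      TRUE ~ NA_character_
    )
  )
  bad <- probes$ies_id[!probes$countable]
  if (length(bad) > 0L) {
    msg <- sprintf("%d IES(s) uncountable at k = %d: %s", length(bad), k,
                   paste(head(bad, 10L), collapse = ", "))
    if (on_uncountable == "error") abort(msg) else warn(msg)
  }
  probes
}
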