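#' Directed-Lobish channel lookup tables
#'
#' Each electrode is assigned a cortical-lobe symbol (F/T/P/O/C for frontal,
#' temporal, parietal, occipital, central; suffix L/R/z for left, right,
#' midline). `lut32` covers the 32-channel 10/20 montage of the
#' mental-performance cap; `lut14` the 14-channel stress cap (which carries no
#' midline or central electrodes, hence an 8-symbol alphabet).
#'
#' @param lut `"lut32"`, `"lut14"`, or a character vector of symbols (one per
#'   channel) drawn from the 14-symbol alphabet.
#' @return Character vector of per-channel symbols with attribute `alphabet`
#'   (the distinct symbols, in first-appearance order of the full symbol set).
#' @examples
#' dlob_lut("lut14")
#' @export
dlob_lut <- function(lut) {
  all_symbols <- c("FL", "FR", "Fz", "TL", "TR", "PL", "PR", "Pz",
                   "OL", "OR", "Oz", "CL", "CR", "Cz")
  if (is.character(lut) && length(lut) == 1L) {
    lut <- switch(lut,
      lut32 = c("Cz", "Fz", "FL", "FL", "FL", "FL", "CL", "FL", "FL", "TL",
                "CL", "CL", "PL", "PL", "PL", "OL", "Pz", "Oz", "OR", "PR",
                "PR", "PR", "CR", "CR", "TR", "FR", "FR", "CR", "FR", "FR",
                "FR", "FR"),
      lut14 = c("FL", "FL", "FL", "FL", "TL", "PL", "OL", "OR", "PR", "TR",
                "FR", "FR", "FR", "FR"),
      abort(sprintf("unknown LUT '%s'; use 'lut32', 'lut14', or a symbol vector.",
                    lut), class = "cubicpat_config_error")
    )
  }
  bad <- setdiff(unique(lut), all_symbols)
  if (length(bad)) {
    abort(sprintf("unknown DLob symbol(s): %s", paste(bad, collapse = ", ")),
          class = "cubicpat_config_error")
  }
  structure(lut, alphabet = intersect(all_symbols, lut))
}

#' Decode a feature index into its channel triplet
#'
#' Inverts the cubic coding by base-`n` digit separation:
#' `ch_j = (floor((value - 1) / n^(j-1)) mod n) + 1` for `j = 1, 2, 3`.
#' Note the digits come out in reverse of the encoding order: encoding ranks
#' `(a, b, c)` produce the 1-based feature index `(a-1) n^2 + (b-1) n + c`,
#' which decodes to `(c, b, a)`.
#'
#' @param value 1-based feature index in `1..n^3`.
#' @param n Channel count.
#' @return Integer vector of three channel indices in `1..n`.
#' @examples
#' decode_feature_index(31, n = 4) # 3 4 2
#' @export
decode_feature_index <- function(value, n) {
  if (any(value < 1L | value > n^3)) {
    abort(sprintf("feature index out of range 1..%d.", n^3),
          class = "cubicpat_index_error")
  }
  v <- value - 1
  as.integer(floor(v / n^(0:2)) %% n) + 1L
}

#' Build a Directed-Lobish symbol sequence from selected features
#'
#' Every selected cubic-pattern feature encodes three channels; decoding the
#' feature index and looking each channel up in the LUT emits three lobe
#' symbols per feature, concatenated over the selected features in their
#' selection order. By default the three decoded digits are reversed so the
#' symbols appear in the original channel-encoding order (rank positions j,
#' j+1, j+2); `symbol_order = "decoded"` keeps the raw digit order instead.
#' Symbol histograms and entropy are unaffected by this choice; transition
#' tables are not, which is why it is explicit.
#'
#' @param selected_indices 1-based feature indices (e.g.
#'   `selection$selected_indices`).
#' @param lut A LUT from [dlob_lut()] (or a name/vector accepted by it).
#' @param symbol_order `"encoding"` (default) or `"decoded"`.
#' @return An object of class `dlob_sequence`: list with `symbols` (length
#'   `3 * length(selected_indices)`), `source_indices`, `n_channels`,
#'   `alphabet`.
#' @examples
#' s <- build_sequence(c(1, 2744), dlob_lut("lut14"))
#' s$symbols
#' @export
build_sequence <- function(selected_indices, lut,
                           symbol_order = c("encoding", "decoded")) {
  symbol_order <- match.arg(symbol_order)
  lut <- dlob_lut(lut)
  n <- length(lut)
  if (length(selected_indices) &&
      any(selected_indices < 1L | selected_indices > n^3)) {
    abort(sprintf("selected feature indices must lie in 1..%d for a %d-channel LUT.",
                  n^3, n),
          class = "cubicpat_index_error")
  }
  symbols <- unlist(lapply(selected_indices, function(v) {
    ch <- decode_feature_index(v, n)
    if (symbol_order == "encoding") ch <- rev(ch)
    lut[ch]
  }), use.names = FALSE)
  structure(list(symbols = as.character(symbols %||% character(0L)),
                 source_indices = as.integer(selected_indices),
                 n_channels = n, alphabet = attr(lut, "alphabet")),
            class = "dlob_sequence")
}

#' @export
print.dlob_sequence <- function(x, ...) {
  cat(sprintf("<dlob_sequence> %d symbols over a %d-symbol alphabet (%d features, %d channels)\n",
              length(x$symbols), length(x$alphabet),
              length(x$source_indices), x$n_channels))
  if (length(x$symbols)) {
    cat(paste(head(x$symbols, 21L), collapse = " "),
        if (length(x$symbols) > 21L) "...\n" else "\n")
  }
  invisible(x)
}

#' Symbol histogram, transition table and entropy of a DLob sequence
#'
#' Counts adjacent symbol pairs into a square transition matrix over the
#' LUT's alphabet (so `sum(counts) == length(sequence) - 1`), the per-symbol
#' histogram, and the Shannon entropy of the histogram in bits.
#'
#' @param seq A `dlob_sequence` (or a bare character vector of symbols, in
#'   which case the alphabet is its sorted unique values).
#' @return An object of class `dlob_transitions`: list with `counts` (square
#'   integer matrix), `histogram` (named counts), `entropy_bits`, `alphabet`.
#' @export
transition_table <- function(seq) {
  if (inherits(seq, "dlob_sequence")) {
    symbols <- seq$symbols
    alphabet <- seq$alphabet
  } else {
    symbols <- as.character(seq)
    alphabet <- sort(unique(symbols))
  }
  k <- length(alphabet)
  counts <- matrix(0L, nrow = k, ncol = k, dimnames = list(alphabet, alphabet))
  histogram <- setNames(tabulate(factor(symbols, levels = alphabet), nbins = k),
                        alphabet)
  m <- length(symbols)
  if (m >= 2L) {
    from <- factor(symbols[-m], levels = alphabet)
    to <- factor(symbols[-1L], levels = alphabet)
    tt <- table(from, to)
    counts[] <- as.integer(tt)
  }
  entropy <- if (sum(histogram) > 0L) sequence_entropy(histogram) else 0
  structure(list(counts = counts, histogram = histogram,
                 entropy_bits = entropy, alphabet = alphabet),
            class = "dlob_transitions")
}

#' @export
print.dlob_transitions <- function(x, ...) {
  cat(sprintf("<dlob_transitions> %d-symbol alphabet, %d transitions, entropy %.4f bits\n",
              length(x$alphabet), sum(x$counts), x$entropy_bits))
  print(x$counts)
  invisible(x)
}

#' @describeIn transition_table tidy method: long tibble of transitions
#'   (`from`, `to`, `count`).
#' @param x,... Method arguments.
#' @method tidy dlob_transitions
#' @export
tidy.dlob_transitions <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) |>
    setNames(c("from", "to", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' @describeIn transition_table glance method: entropy, alphabet size,
#'   complexity percent.
#' @method glance dlob_transitions
#' @export
glance.dlob_transitions <- function(x, ...) {
  tibble(entropy_bits = x$entropy_bits,
         alphabet_size = length(x$alphabet),
         complexity_percent = complexity_ratio(x$entropy_bits,
                                               length(x$alphabet)))
}

#' @describeIn transition_table transition heat-map.
#' @param object A `dlob_transitions`.
#' @method autoplot dlob_transitions
#' @export
autoplot.dlob_transitions <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$to, y = .data$from,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev(object$alphabet)) +
    ggplot2::labs(x = "to", y = "from", title = "DLob symbol transitions") +
    ggplot2::theme_minimal()
}

#' Shannon entropy of a symbol histogram
#'
#' `-sum(p * log2(p))` over the nonzero bins, in bits. Maximal
#' (`log2(n_bins)`) for a uniform histogram, zero when all mass sits on one
#' symbol.
#'
#' @param histogram Nonnegative counts (or proportions) with positive total.
#' @return Entropy in bits.
#' @examples
#' sequence_entropy(rep(1, 14)) # log2(14) = 3.8074
#' @export
sequence_entropy <- function(histogram) {
  h <- as.numeric(histogram)
  if (any(h < 0)) {
    abort("histogram counts must be nonnegative.", class = "cubicpat_data_error")
  }
  tot <- sum(h)
  if (tot <= 0) {
    abort("histogram total must be positive.", class = "cubicpat_data_error")
  }
  p <- h[h > 0] / tot
  -sum(p * log2(p))
}

#' Complexity ratio of a symbol sequence
#'
#' Entropy expressed as a percentage of the maximum achievable with the given
#' alphabet: `100 * entropy_bits / log2(alphabet_size)`.
#'
#' @param entropy_bits Shannon entropy in bits.
#' @param alphabet_size Number of distinct symbols available (>= 2).
#' @return Percentage in `[0, 100]`.
#' @examples
#' complexity_ratio(3.4974, 14) # 91.86
#' @export
complexity_ratio <- function(entropy_bits, alphabet_size) {
  if (alphabet_size < 2L) {
    abort("`alphabet_size` must be >= 2.", class = "cubicpat_config_error")
  }
  emax <- log2(alphabet_size)
  if (entropy_bits > emax + 1e-9) {
    abort(sprintf("entropy %.4f exceeds the %d-symbol maximum %.4f.",
                  entropy_bits, alphabet_size, emax),
          class = "cubicpat_invariant_error")
  }
  if (entropy_bits < 0) {
    abort("entropy must be nonnegative.", class = "cubicpat_invariant_error")
  }
  100 * entropy_bits / emax
}

#' Export the cortical connectome graph
#'
#' Builds the directed weighted graph whose nodes are the lobe symbols with
#' nonzero histogram counts and whose edge weights are the transition counts,
#' and writes it as GraphML or DOT.
#'
#' @param table A `dlob_transitions`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return The [igraph::graph] object, invisibly.
#' @export
export_connectome <- function(table, path, format = c("graphml", "dot")) {
  stopifnot(inherits(table, "dlob_transitions"))
  if (!is.character(format) || !format[1L] %in% c("graphml", "dot")) {
    abort(sprintf("unknown connectome format '%s'; supported: graphml, dot.",
                  format[1L]),
          class = "cubicpat_config_error")
  }
  format <- match.arg(format)
  g <- connectome_graph(table)
  igraph::write_graph(g, path, format = format)
  invisible(g)
}

#' @rdname export_connectome
#' @export
connectome_graph <- function(table) {
  stopifnot(inherits(table, "dlob_transitions"))
  active <- names(table$histogram)[table$histogram > 0L]
  sub <- table$counts[active, active, drop = FALSE]
  igraph::graph_from_adjacency_matrix(sub, mode = "directed", weighted = TRUE,
                                      diag = TRUE)
}
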