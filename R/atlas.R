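#' @importFrom stats cor pt qt sd var rnorm p.adjust complete.cases
#' @importFrom utils head read.csv read.delim write.csv write.table combn
NULL

# The 45 bilateral region codes of the 90-region automated anatomical
# labeling (AAL) cerebral parcellation, in AAL numerical order. Each code
# expands to a left (odd AAL index) and right (even AAL index) region.
.aal_codes <- c(
  "PreCG", "SFG", "SFGorb", "MFG", "MFGorb", "IFGoper", "IFGtri", "IFGorb",
  "ROL", "SMA", "OLF", "SFGmed", "SFGmorb", "REC", "INS", "ACG", "MCG",
  "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING", "SOG", "MOG", "IOG",
  "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG", "PCUN", "PCL", "CAU", "PUT",
  "PAL", "THA", "HES", "STG", "TPOsup", "MTG", "TPOmid", "ITG"
)

# Resting-state functional network membership per region code. ITG is the
# one laterality-split code: the right inferior temporal gyrus sits in the
# attention network, the left one in the default mode network.
.network_of_code <- c(
  CAL = "VN", CUN = "VN", LING = "VN", SOG = "VN", MOG = "VN", IOG = "VN",
  FFG = "VN",
  PreCG = "SMN", ROL = "SMN", PoCG = "SMN", PCL = "SMN", HES = "SMN",
  STG = "SMN",
  SPG = "AN", SMA = "AN", INS = "AN", MCG = "AN", SMG = "AN", PUT = "AN",
  PAL = "AN",
  MFG = "FPN", MFGorb = "FPN", IFGoper = "FPN", IFGtri = "FPN", IPL = "FPN",
  SFGorb = "LS", OLF = "LS", REC = "LS", AMYG = "LS", CAU = "LS", THA = "LS",
  TPOsup = "LS", TPOmid = "LS",
  SFG = "DMN", SFGmed = "DMN", SFGmorb = "DMN", IFGorb = "DMN", ACG = "DMN",
  PCG = "DMN", HIP = "DMN", PHG = "DMN", ANG = "DMN", PCUN = "DMN",
  MTG = "DMN"
)

#' Functional network names in canonical order
#'
#' @return Character vector of the six resting-state network codes: visual
#'   (VN), somatomotor (SMN), attention (AN, the merged dorsal + ventral
#'   attention networks), frontoparietal (FPN), limbic (LS) and default mode
#'   (DMN).
#' @export
network_levels <- function() c("VN", "SMN", "AN", "FPN", "LS", "DMN")

#' Build the default 90-region atlas
#'
#' Constructs the 90-region AAL cerebral parcellation with each region
#' assigned to one of six resting-state functional networks. Regions are
#' stored in AAL numerical order (odd = left, even = right) and labelled
#' `CODE.L` / `CODE.R`. Every region code is bilateral within one network
#' except the inferior temporal gyrus, whose right side belongs to the
#' attention network and left side to the default mode network.
#'
#' @return A data.frame of class `fc_atlas` with columns `index` (1-based
#'   region index), `label`, `hemisphere` (`"L"`/`"R"`) and `network`
#'   (factor over [network_levels()]).
#' @examples
#' atlas <- build_default_atlas()
#' table(atlas$network)
#' @export
build_default_atlas <- function() {
  code <- rep(.aal_codes, each = 2)
  hemi <- rep(c("L", "R"), times = length(.aal_codes))
  network <- .network_of_code[code]
  # laterality-split assignment for ITG
  network[code == "ITG" & hemi == "R"] <- "AN"
  network[code == "ITG" & hemi == "L"] <- "DMN"
  atlas <- data.frame(
    index = seq_along(code),
    label = paste(code, hemi, sep = "."),
    hemisphere = hemi,
    network = factor(network, levels = network_levels()),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("fc_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' Validate an atlas
#'
#' Checks the structural invariants of a region atlas: unique labels, a
#' single network per region, and (for 90-region atlases) the expected
#' per-network region counts after bilateral expansion.
#'
#' @param atlas An atlas data.frame as returned by [build_default_atlas()].
#' @return The atlas, invisibly; errors on violation.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas),
            all(c("index", "label", "hemisphere", "network") %in% names(atlas)))
  if (anyDuplicated(atlas$label))
    stop("atlas labels must be unique")
  if (!all(atlas$index == seq_len(nrow(atlas))))
    stop("atlas index must be 1..n_regions in order")
  if (any(is.na(atlas$network)))
    stop("every region must belong to exactly one network")
  if (nrow(atlas) == 90L) {
    sizes <- table(factor(atlas$network, levels = network_levels()))
    expected <- c(VN = 14L, SMN = 12L, AN = 15L, FPN = 10L, LS = 16L,
                  DMN = 23L)
    if (!all(sizes == expected))
      stop("90-region atlas has unexpected network sizes: ",
           paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  invisible(atlas)
}

#' Canonical edge index of a region pair
#'
#' Maps an unordered region pair to its position in the canonical row-major
#' upper-triangle edge order: (1,2), (1,3), ..., (1,n), (2,3), ... All
#' modules share this single bijection, so edge indices never drift between
#' stages.
#'
#' @param i,j Region indices in 1..n (vectorised); `i != j`, order ignored.
#' @param n Number of regions.
#' @return Integer edge index in 1..n(n-1)/2.
#' @examples
#' edge_index(1, 2, 90)   # 1
#' edge_index(89, 90, 90) # 4005
#' @export
edge_index <- function(i, j, n) {
  stopifnot(n >= 2)
  if (any(i < 1 | i > n | j < 1 | j > n))
    stop("region indices out of range 1..", n)
  if (any(i == j))
    stop("edge requires two distinct regions")
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  as.integer((lo - 1) * n - lo * (lo + 1) / 2 + hi)
}

#' Region pair of a canonical edge index
#'
#' Inverse of [edge_index()]: recovers the (i, j) region pair, i < j, of a
#' canonical edge index.
#'
#' @param k Edge index in 1..n(n-1)/2 (vectorised).
#' @param n Number of regions.
#' @return A two-column integer matrix with columns `i` and `j`.
#' @export
pair_of_edge <- function(k, n) {
  stopifnot(n >= 2)
  E <- n * (n - 1) / 2
  if (any(k < 1 | k > E))
    stop("edge index out of range 1..", E)
  # cumulative edge count after finishing row i: i*n - i*(i+1)/2
  ends <- seq_len(n - 1) * n - seq_len(n - 1) * (seq_len(n - 1) + 1) / 2
  i <- findInterval(k - 1, ends) + 1L
  j <- as.integer(k - ((i - 1) * n - i * (i + 1) / 2))
  cbind(i = as.integer(i), j = j)
}

#' Number of edges for an n-region parcellation
#' @param n Number of regions.
#' @return n(n-1)/2.
#' @export
n_edges <- function(n) as.integer(n * (n - 1) / 2)

#' Human-readable labels for canonical edges
#'
#' @param atlas An atlas.
#' @param k Edge indices (default: all).
#' @return Character vector `"label_i--label_j"` in canonical edge order.
#' @export
edge_labels <- function(atlas, k = seq_len(n_edges(nrow(atlas)))) {
  p <- pair_of_edge(k, nrow(atlas))
  paste(atlas$label[p[, "i"]], atlas$label[p[, "j"]], sep = "--")
}

#' Possible edge counts per network pair
#'
#' Counts, for every unordered pair of functional networks (A, B), the
#' number of region pairs with one endpoint in A and one in B; the diagonal
#' (A = B) counts within-network pairs C(|A|, 2). These denominators
#' standardize selected-edge counts into percentages.
#'
#' @param atlas An atlas.
#' @return A data.frame with columns `network_a`, `network_b` (ordered by
#'   canonical network order, `network_a` <= `network_b`), `type`
#'   (`"intra"`/`"inter"`) and `n_possible`. Counts sum to n(n-1)/2.
#' @examples
#' pc <- possible_edge_counts(build_default_atlas())
#' sum(pc$n_possible)                       # 4005
#' sum(pc$n_possible[pc$type == "intra"])   # 680
#' @export
possible_edge_counts <- function(atlas) {
  validate_atlas(atlas)
  lv <- levels(atlas$network)
  sizes <- table(atlas$network)
  pairs <- expand.grid(a = seq_along(lv), b = seq_along(lv))
  pairs <- pairs[pairs$a <= pairs$b, ]
  n_possible <- ifelse(
    pairs$a == pairs$b,
    choose(sizes[pairs$a], 2),
    sizes[pairs$a] * sizes[pairs$b]
  )
  out <- data.frame(
    network_a = factor(lv[pairs$a], levels = lv),
    network_b = factor(lv[pairs$b], levels = lv),
    type = ifelse(pairs$a == pairs$b, "intra", "inter"),
    n_possible = as.integer(n_possible),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write / read an atlas as TSV
#'
#' @param atlas An atlas.
#' @param path File path.
#' @return `write_atlas` returns the path invisibly; `read_atlas` returns
#'   the atlas.
#' @export
write_atlas <- function(atlas, path) {
  write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- read.delim(path, stringsAsFactors = FALSE)
  atlas$network <- factor(atlas$network, levels = network_levels())
  class(atlas) <- c("fc_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}
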