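# Orthogonal discrete wavelet transform (Mallat pyramid) with periodized
# signal extension, supporting the Daubechies, Symlet and Coiflet families.
# Periodization keeps the transform square (exactly n coefficients for n
# samples) and orthogonal, so perfect reconstruction and the Parseval
# identity hold to machine precision -- both are relied on by the
# wavelet-perturbation augmentation and its audits.

# standard decomposition low-pass filters; the other three filters of each
# quadrature-mirror bank are derived below
.dec_lo_table <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794, 0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458, 0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309, -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744, 0.077571493840045719, -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.72430852843777294, 0.60382926979718965, 0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613, -0.03158203931748603, 0.027522865530305727, 0.097501605587323043, -0.12976686756726194, -0.22626469396543983, 0.31525035170919763, 0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.00042957797292136651, 0.01255099855609984, -0.016574541630666881, -0.038029936935014413, 0.080612609151083078, 0.071309219266830259, -0.22403618499387498, -0.14390600392856498, 0.46978228740519312, 0.72913209084623509, 0.39653931948191729, 0.077852054085009184),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705, -0.0048703529934515741, 0.0087460940474057766, 0.013981027917398282, -0.044088253930794755, -0.017369301001807547, 0.12874742662047847, 0.00047248457391328279, -0.28401554296154691, -0.015829105256349306, 0.58535468365420673, 0.67563073629728976, 0.31287159091429995, 0.054415842243104008),
  db9 = c(3.9347320316271603e-05, -0.00025196318894271012, 0.00023038576352319597, 0.0018476468830562265, -0.0042815036824634303, -0.0047232047577513972, 0.022361662123679096, 0.00025094711483145197, -0.067632829061329974, 0.03072568147933338, 0.14854074933810638, -0.096840783222976456, -0.29327378327917492, 0.13319738582500756, 0.65728807805130052, 0.60482312369011115, 0.24383467461259034, 0.038077947363878345),
  db10 = c(-1.3264202894521244e-05, 9.3588670320069592e-05, -0.00011646685512928545, -0.00068585669495971162, 0.0019924052951850561, 0.0013953517470529011, -0.010733175483330575, 0.0036065535669561697, 0.033212674059341002, -0.029457536821875813, -0.071394147166397082, 0.093057364603572348, 0.12736934033579325, -0.19594627437737705, -0.24984642432731538, 0.28117234366057747, 0.68845903945360354, 0.52720118893172563, 0.1881768000776915, 0.026670057900555554),
  sym2 = c(-0.12940952255092145, 0.22414386804185735, 0.83651630373746899, 0.48296291314469025),
  sym3 = c(0.035226291882100656, -0.085441273882241486, -0.13501102001039084, 0.45987750211933132, 0.80689150931333875, 0.33267055295095688),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545, 0.80373875180591614, 0.29785779560527736, -0.099219543576847216, -0.012603967262037833, 0.032223100604042702),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936, 0.72340769040242059, 0.63397896345821192, 0.016602105764522319, -0.17532808990845047, -0.021101834024758855, 0.019538882735286728),
  sym6 = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057, -0.048311742585632998, 0.49105594192674662, 0.787641141030194, 0.3379294217276218, -0.072637522786462516, -0.021060292512300564, 0.044724901770665779, 0.0017677118642428036, -0.007800708325034148),
  sym7 = c(0.0026818145682578781, -0.0010473848886829163, -0.01263630340325193, 0.03051551316596357, 0.067892693501372697, -0.049552834937127255, 0.017441255086855827, 0.5361019170917628, 0.76776431700316405, 0.28862963175151463, -0.14004724044296152, -0.10780823770381774, 0.0040102448715336634, 0.010268176708511255),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981, 0.0076074873249176054, -0.14329423835080971, -0.061273359067658524, 0.48135965125837221, 0.77718575170052351, 0.3644418948353314, -0.051945838107709037, -0.027219029917056003, 0.049137179673607506, 0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668, 0.0018899503327594609),
  sym9 = c(0.0014009155259146807, 0.00061978088898558676, -0.013271967781817119, -0.01152821020767923, 0.03022487885827568, 0.00058346274612580684, -0.054568958430834071, 0.238760914607303, 0.717897082764412, 0.61733844914093583, 0.035272488035271894, -0.19155083129728512, -0.018233770779395985, 0.06207778930288603, 0.0088592674934004842, -0.010264064027633142, -0.00047315449868008311, 0.0010694900329086053),
  sym10 = c(0.00077015980911449011, 9.5632670722894754e-05, -0.0086412992770224222, -0.0014653825813050513, 0.045927239231092203, 0.011609893903711381, -0.15949427888491757, -0.070880535783243853, 0.47169066693843925, 0.7695100370211071, 0.38382676106708546, -0.035536740473817552, -0.0319900568824278, 0.049994972077376687, 0.0057649120335819086, -0.02035493981231129, -0.00080435893201654491, 0.0045931735853118284, 5.7036083618494284e-05, -0.00045932942100465878),
  coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.38486484686485778, 0.85257202021160039, 0.33789766245748182, -0.07273261951252645),
  coif2 = c(-0.00072054944552034698, -0.0018232088709110323, 0.0056114348193688343, 0.02368017194684777, -0.059434418646431092, -0.076488599078280761, 0.41700518442323908, 0.81272363544941351, 0.38611006682276289, -0.067372554723725595, -0.041464936786871777, 0.016387336463203641),
  coif3 = c(-3.4599773197272781e-05, -7.0983302506379004e-05, 0.00046621695982040288, 0.0011175187708306303, -0.0025745176881367972, -0.0090079761367306242, 0.015880544863669452, 0.034555027573297738, -0.082301927106299827, -0.071799821619154838, 0.42848347637737, 0.79377722262608719, 0.40517690240911824, -0.061123390002972552, -0.065771911281469364, 0.023452696142077168, 0.0077825964256727463, -0.0037935128643808019),
  coif4 = c(-1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05, 6.2338854312787192e-05, -0.00025997433712225682, -0.00058902022463321654, 0.0012665610789256603, 0.0037514346971460866, -0.0056582838001308835, -0.015211728187697211, 0.025082253337949612, 0.039334422605589149, -0.096220424535952642, -0.066627472366817167, 0.43438603311435653, 0.78223893442428261, 0.41530842700068227, -0.056077319603569258, -0.081266710249193727, 0.02668230466960483, 0.016068947131575029, -0.0073461679362680507, -0.001629492425226786, 0.00089231390253700297),
  coif5 = c(-9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06, -2.1270221672515614e-05, -4.1219861924265501e-05, 0.00014035632812373243, 0.00030185794166824478, -0.00063755892612588115, -0.0016616273039298788, 0.0024315754425382886, 0.0067615202206204169, -0.0091595073386761625, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834, -0.10556315130733723, -0.06203775157498196, 0.43798230665916338, 0.77429362286032744, 0.42157126673075435, -0.052046670253554764, -0.091921588060086087, 0.028169744270532353, 0.023408322118927783, -0.010131584846900276, -0.0041593126275786402, 0.0021782943778456947, 0.00035857774116175768, -0.000212081862067494)
)

#' Supported orthogonal wavelets
#'
#' @return Character vector of wavelet names (`db1`–`db10`, `sym2`–`sym10`,
#'   `coif1`–`coif5`).
#' @export
supported_wavelets <- function() names(.dec_lo_table)

#' Quadrature-mirror filter bank of an orthogonal wavelet
#'
#' @param wavelet wavelet name, one of [supported_wavelets()].
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` filter vectors.
#' @export
wavelet_filters <- function(wavelet) {
  dec_lo <- .dec_lo_table[[wavelet]]
  if (is.null(dec_lo))
    stop_config("unknown wavelet '", wavelet, "'; supported: ",
                paste(supported_wavelets(), collapse = ", "))
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L))
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
}

#' Maximum useful decomposition level
#'
#' Largest level for which the periodized approximation band still has at
#' least as many coefficients as the filter length.
#'
#' @param n signal length in samples.
#' @param wavelet wavelet name.
#' @return Integer level (possibly 0 for very short signals).
#' @export
max_dwt_level <- function(n, wavelet) {
  L <- length(wavelet_filters(wavelet)$dec_lo)
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

# circular index helper: ((i mod n) + n) mod n, 0-based in, 1-based out
.cidx <- function(i, n) ((i %% n) + n) %% n + 1L

# one periodized analysis step; x is padded to even length by repeating the
# last sample (original length is restored at reconstruction)
.dwt_step <- function(x, filt) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  half <- n %/% 2L
  L <- length(filt$dec_lo)
  shift <- L %/% 2L
  ca <- numeric(half); cd <- numeric(half)
  base <- 2L * (seq_len(half) - 1L) + shift
  for (m in seq_len(L) - 1L) {
    xi <- x[.cidx(base - m, n)]
    ca <- ca + filt$dec_lo[m + 1L] * xi
    cd <- cd + filt$dec_hi[m + 1L] * xi
  }
  list(ca = ca, cd = cd)
}

# one periodized synthesis step, returning a vector of length 2*length(ca)
.idwt_step <- function(ca, cd, filt) {
  half <- length(ca)
  n <- 2L * half
  L <- length(filt$rec_lo)
  up_a <- numeric(n); up_d <- numeric(n)
  up_a[seq(1L, n, by = 2L)] <- ca
  up_d[seq(1L, n, by = 2L)] <- cd
  shift <- L %/% 2L - 1L
  out <- numeric(n)
  base <- (seq_len(n) - 1L) + shift
  for (m in seq_len(L) - 1L) {
    idx <- .cidx(base - m, n)
    out <- out + filt$rec_lo[m + 1L] * up_a[idx] + filt$rec_hi[m + 1L] * up_d[idx]
  }
  out
}

#' Multi-level discrete wavelet decomposition
#'
#' Periodized orthogonal DWT of a single channel. The coefficient layout
#' mirrors the usual pyramid: one approximation band at the deepest level
#' plus one detail band per level.
#'
#' @param x numeric vector.
#' @param wavelet wavelet name, one of [supported_wavelets()].
#' @param level decomposition depth, `1 <= level <= max_dwt_level()`.
#' @return List with `ca` (deepest approximation), `cd` (list of detail
#'   bands, deepest first), `lengths` (per-level input lengths, needed to
#'   undo the odd-length padding), `wavelet`, `level`.
#' @seealso [wave_rec()], [wavelet_perturb()]
#' @export
wave_dec <- function(x, wavelet, level) {
  filt <- wavelet_filters(wavelet)
  level <- as.integer(level)
  if (level < 1L) stop_config("decomposition level must be >= 1")
  lmax <- max_dwt_level(length(x), wavelet)
  if (level > lmax)
    stop_config("level ", level, " too deep for ", length(x), " samples with ",
                wavelet, " (max ", lmax, ")")
  cds <- vector("list", level)
  lens <- integer(level)
  cur <- x
  for (l in seq_len(level)) {
    lens[l] <- length(cur)
    st <- .dwt_step(cur, filt)
    cds[[l]] <- st$cd
    cur <- st$ca
  }
  list(ca = cur, cd = rev(cds), lengths = rev(lens),
       wavelet = wavelet, level = level)
}

#' Multi-level inverse discrete wavelet transform
#'
#' Inverts [wave_dec()]; with untouched coefficients the reconstruction is
#' exact to machine precision.
#'
#' @param dec a decomposition as returned by [wave_dec()].
#' @return Numeric vector of the original length.
#' @export
wave_rec <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  cur <- dec$ca
  for (l in seq_len(dec$level)) {
    cur <- .idwt_step(cur, dec$cd[[l]], filt)
    cur <- cur[seq_len(dec$lengths[l])]
  }
  cur
}
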