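# Small shared fixtures, built in code.

tinyGrid <- function(nADC = 3, nT2 = 2) {
  spectralGrid(ADC = exp(seq(log(1e-3), log(0.1), length.out = nADC)),
               T2star = exp(seq(log(0.05), log(0.15), length.out = nT2)))
}

tinyProtocol <- function(bs = c(0, 0, 200, 800), TEs = c(80, 160)) {
  acquisitionProtocol(data.frame(b = rep(bs, times = length(TEs)),
                                 TE = rep(TEs, each = length(bs))),
                      teUnit = "ms")
}

# small protocol with the placental structure but fewer volumes
smallProtocol <- function() placentalProtocol(nB = 10, TEs = c(78, 150, 222))

# weight permutation matching fitted components to phantom truth by
# log-distance between spectral modes
matchComponents <- function(fit, phantom) {
  tm <- componentModes(canonicalComponents(phantom))
  fm <- componentModes(canonicalComponents(fit))
  apply(tm, 1, function(r) which.min(colSums((t(log(fm)) - log(r))^2)))
}
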