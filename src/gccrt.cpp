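#include <Rcpp.h>
using namespace Rcpp;

// Single-scatter event accumulation for the collimator-free geometry.
//
// Vertices N run over the supplied lattice, sources S over the activity
// voxels, detector pixels D over the detector grid. Each (S, N, D) triple
// contributes to the angle bin containing its exact scattering angle (the
// angle between S->N and N->D), with weight
//   w = volS / (4 pi SN^2) * 1/(SN * dOmega_b) * K_b * volN / ND^2
//       * exp(-mu (SN + ND)),
// the same convention as the collimated projector, so the collimated event
// set (N on the vertical axis through D) is a subset with equal weights.
//
// mode 0: returns the projection array (npix, npix, nbin) for activity f.
// mode 1: returns the dense weight matrix (npix*npix*nbin) x nvox
//         (f is ignored; each voxel contributes with unit activity).
// [[Rcpp::export]]
NumericVector gccrt_accumulate(NumericVector f,
                               NumericMatrix src,   // nvox x 3 voxel centres
                               NumericMatrix ver,   // nver x 3 vertex nodes
                               NumericMatrix pix,   // npix x 2 pixel centres
                               NumericVector edges, // nbin + 1 angle edges
                               NumericVector Kb,    // nbin kinematic factors
                               double guard,        // exclusion band at pi/2
                               double volS, double volN, double mu,
                               int mode) {
  const int nvox = src.nrow(), nver = ver.nrow(), npix = pix.nrow();
  const int nbin = Kb.size();
  const double fourpi = 4.0 * M_PI;
  std::vector<double> dwk(nbin);
  for (int b = 0; b < nbin; ++b) dwk[b] = edges[b + 1] - edges[b];

  NumericVector out;
  if (mode == 0) out = NumericVector(npix * nbin);
  else out = NumericVector((R_xlen_t)npix * nbin * nvox);

  for (int n = 0; n < nver; ++n) {
    const double nx = ver(n, 0), ny = ver(n, 1), nz = ver(n, 2);
    // outgoing legs to every pixel
    std::vector<double> vx(npix), vy(npix), vz(npix), nd2(npix);
    for (int d = 0; d < npix; ++d) {
      vx[d] = pix(d, 0) - nx; vy[d] = pix(d, 1) - ny; vz[d] = -nz;
      nd2[d] = vx[d] * vx[d] + vy[d] * vy[d] + nz * nz;
    }
    for (int s = 0; s < nvox; ++s) {
      const double fs = (mode == 0) ? f[s] : 1.0;
      if (mode == 0 && fs == 0.0) continue;
      const double ux = nx - src(s, 0), uy = ny - src(s, 1),
                   uz = nz - src(s, 2);
      const double sn2 = ux * ux + uy * uy + uz * uz;
      if (sn2 <= 0.0) continue;   // vertex coincides with the source voxel
      const double sn = std::sqrt(sn2);
      const double base = fs * volS * volN / (fourpi * sn2 * sn);
      const double attS = (mu > 0.0) ? std::exp(-mu * sn) : 1.0;
      for (int d = 0; d < npix; ++d) {
        // scattering angle between propagation directions S->N and N->D
        const double dot = ux * vx[d] + uy * vy[d] + uz * vz[d];
        double c = dot / (sn * std::sqrt(nd2[d]));
        if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
        const double theta = std::acos(c);
        if (guard > 0.0 && std::fabs(theta - M_PI_2) < guard) continue;
        if (theta <= edges[0] || theta > edges[nbin]) continue;
        int b = int(std::upper_bound(edges.begin(), edges.end(), theta) -
                    edges.begin()) - 1;
        if (b < 0 || b >= nbin) continue;
        double w = base * Kb[b] / (dwk[b] * nd2[d]);
        if (mu > 0.0) w *= attS * std::exp(-mu * std::sqrt(nd2[d]));
        if (mode == 0)
          out[d + (R_xlen_t)npix * b] += w;
        else
          out[d + (R_xlen_t)npix * b + (R_xlen_t)npix * nbin * s] += w;
      }
    }
  }
  return out;
}
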