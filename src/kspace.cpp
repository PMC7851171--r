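// k-space pseudospectral solver for linear acoustics in heterogeneous
// media (1D / 2D), first-order coupled equations with a split-field
// perfectly-matched-layer-style absorbing sponge and spatially staggered
// derivative operators. Spatial derivatives are evaluated spectrally with
// the k-space correction sinc(c_ref k dt / 2), which makes the scheme
// exact for homogeneous media.
#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <vector>
#include <cmath>

using cplx = std::complex<double>;

static inline double sinc(double z) {
  return (std::abs(z) < 1e-12) ? 1.0 : std::sin(z) / z;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix kspace_solve(Rcpp::NumericMatrix p0,
                                 Rcpp::NumericMatrix c2,
                                 Rcpp::NumericMatrix rho,
                                 double dx, double dy, double dt,
                                 int nsteps, double c_ref,
                                 Rcpp::IntegerVector sensor_idx,
                                 int pml_size = 20,
                                 double pml_alpha = 2.0,
                                 int record_every = 1,
                                 double pml_power = 2.0) {
  const int nx = p0.nrow(), ny = p0.ncol();
  const bool two_d = ny > 1;
  const size_t N = size_t(nx) * ny;
  const int ns = sensor_idx.size();
  const int nrec = (nsteps + record_every - 1) / record_every;
  Rcpp::NumericMatrix out(nrec, ns);

  // wavenumbers
  std::vector<double> kx(nx), ky(ny);
  for (int i = 0; i < nx; ++i) {
    int ii = (i <= nx / 2) ? i : i - nx;
    kx[i] = 2.0 * M_PI * ii / (nx * dx);
  }
  if (nx % 2 == 0) kx[nx / 2] = 0.0;   // zero Nyquist in odd derivative
  for (int j = 0; j < ny; ++j) {
    int jj = (j <= ny / 2) ? j : j - ny;
    ky[j] = two_d ? 2.0 * M_PI * jj / (ny * dy) : 0.0;
  }
  if (two_d && ny % 2 == 0) ky[ny / 2] = 0.0;

  // derivative multipliers with k-space correction and half-cell stagger
  std::vector<cplx> DXp(N), DXm(N), DYp(N), DYm(N);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double km = std::sqrt(kx[i] * kx[i] + ky[j] * ky[j]);
      double kap = sinc(c_ref * km * dt / 2.0);
      cplx ikxk(0.0, kx[i] * kap), ikyk(0.0, ky[j] * kap);
      cplx shx = std::exp(cplx(0.0, kx[i] * dx / 2.0));
      cplx shy = std::exp(cplx(0.0, ky[j] * dy / 2.0));
      size_t id = size_t(j) * nx + i;
      DXp[id] = ikxk * shx;
      DXm[id] = ikxk / shx;
      DYp[id] = ikyk * shy;
      DYm[id] = ikyk / shy;
    }
  }

  // PML damping factors (quartic profile, applied twice per update)
  std::vector<double> fx(nx, 1.0), fy(ny, 1.0);
  for (int i = 0; i < nx; ++i) {
    double d = 0.0;
    if (i < pml_size) d = double(pml_size - i) / pml_size;
    else if (i >= nx - pml_size) d = double(i - (nx - pml_size - 1)) / pml_size;
    if (d > 0.0)
      fx[i] = std::exp(-pml_alpha * std::pow(d, pml_power) * c_ref / dx * dt / 2.0);
  }
  if (two_d) {
    for (int j = 0; j < ny; ++j) {
      double d = 0.0;
      if (j < pml_size) d = double(pml_size - j) / pml_size;
      else if (j >= ny - pml_size) d = double(j - (ny - pml_size - 1)) / pml_size;
      if (d > 0.0)
        fy[j] = std::exp(-pml_alpha * std::pow(d, pml_power) * c_ref / dy * dt / 2.0);
    }
  }

  // staggered-density reciprocals and fields
  std::vector<double> irho_sgx(N), irho_sgy(N), rho0(N), c2v(N);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t id = size_t(j) * nx + i;
      rho0[id] = rho(i, j);
      c2v[id] = c2(i, j);
      int ip = (i + 1) % nx, jp = (j + 1) % ny;
      irho_sgx[id] = 2.0 / (rho(i, j) + rho(ip, j));
      irho_sgy[id] = 2.0 / (rho(i, j) + rho(i, jp));
    }

  std::vector<double> ux(N, 0.0), uy(N, 0.0), rhox(N), rhoy(N), p(N);
  const double split = two_d ? 2.0 : 1.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t id = size_t(j) * nx + i;
      p[id] = p0(i, j);
      rhox[id] = p0(i, j) / (split * c2v[id]);
      rhoy[id] = two_d ? rhox[id] : 0.0;
    }

  // FFT work buffers and plans (in-place, column-major: x fastest)
  std::vector<cplx> work(N), work2(N);
  fftw_complex* W = reinterpret_cast<fftw_complex*>(work.data());
  fftw_complex* W2 = reinterpret_cast<fftw_complex*>(work2.data());
  fftw_plan fwd, bwd, fwd2, bwd2;
  unsigned flags = FFTW_MEASURE;
  if (two_d) {
    fwd = fftw_plan_dft_2d(ny, nx, W, W, FFTW_FORWARD, flags);
    bwd = fftw_plan_dft_2d(ny, nx, W, W, FFTW_BACKWARD, flags);
    fwd2 = fftw_plan_dft_2d(ny, nx, W2, W2, FFTW_FORWARD, flags);
    bwd2 = fftw_plan_dft_2d(ny, nx, W2, W2, FFTW_BACKWARD, flags);
  } else {
    fwd = fftw_plan_dft_1d(nx, W, W, FFTW_FORWARD, flags);
    bwd = fftw_plan_dft_1d(nx, W, W, FFTW_BACKWARD, flags);
    fwd2 = fftw_plan_dft_1d(nx, W2, W2, FFTW_FORWARD, flags);
    bwd2 = fftw_plan_dft_1d(nx, W2, W2, FFTW_BACKWARD, flags);
  }
  const double invN = 1.0 / double(N);

  for (int n = 0; n < nsteps; ++n) {
    // gradient of p (packed: d/dx in Re, d/dy in Im after inverse FFT)
    for (size_t id = 0; id < N; ++id) work[id] = cplx(p[id], 0.0);
    fftw_execute(fwd);
    if (two_d) {
      for (size_t id = 0; id < N; ++id)
        work[id] = DXp[id] * work[id] + cplx(0.0, 1.0) * (DYp[id] * work[id]);
    } else {
      for (size_t id = 0; id < N; ++id) work[id] = DXp[id] * work[id];
    }
    fftw_execute(bwd);

    const double dtu = (n == 0) ? dt / 2.0 : dt;  // leapfrog start
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        size_t id = size_t(j) * nx + i;
        double dpdx = work[id].real() * invN;
        ux[id] = fx[i] * (fx[i] * ux[id] - dtu * irho_sgx[id] * dpdx);
        if (two_d) {
          double dpdy = work[id].imag() * invN;
          uy[id] = fy[j] * (fy[j] * uy[id] - dtu * irho_sgy[id] * dpdy);
        }
      }
    }

    // divergence terms
    if (two_d) {
      for (size_t id = 0; id < N; ++id) work2[id] = cplx(ux[id], uy[id]);
      fftw_execute(fwd2);
      // Hermitian split of the packed transform, then packed inverse
      for (int j = 0; j < ny; ++j) {
        int jr = (ny - j) % ny;
        for (int i = 0; i < nx; ++i) {
          int ir = (nx - i) % nx;
          size_t id = size_t(j) * nx + i;
          size_t idr = size_t(jr) * nx + ir;
          if (id > idr) continue;           // handle pairs once
          cplx F = work2[id], G = std::conj(work2[idr]);
          cplx uxh = 0.5 * (F + G);
          cplx uyh = cplx(0.0, -0.5) * (F - G);
          cplx Fr = work2[idr], Gr = std::conj(work2[id]);
          cplx uxhr = 0.5 * (Fr + Gr);
          cplx uyhr = cplx(0.0, -0.5) * (Fr - Gr);
          work[id] = DXm[id] * uxh + cplx(0.0, 1.0) * (DYm[id] * uyh);
          work[idr] = DXm[idr] * uxhr + cplx(0.0, 1.0) * (DYm[idr] * uyhr);
        }
      }
      fftw_execute(bwd);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = size_t(j) * nx + i;
          double duxdx = work[id].real() * invN;
          double duydy = work[id].imag() * invN;
          rhox[id] = fx[i] * (fx[i] * rhox[id] - dt * rho0[id] * duxdx);
          rhoy[id] = fy[j] * (fy[j] * rhoy[id] - dt * rho0[id] * duydy);
          p[id] = c2v[id] * (rhox[id] + rhoy[id]);
        }
    } else {
      for (size_t id = 0; id < N; ++id) work[id] = cplx(ux[id], 0.0);
      fftw_execute(fwd);
      for (size_t id = 0; id < N; ++id) work[id] = DXm[id] * work[id];
      fftw_execute(bwd);
      for (int i = 0; i < nx; ++i) {
        double duxdx = work[i].real() * invN;
        rhox[i] = fx[i] * (fx[i] * rhox[i] - dt * rho0[i] * duxdx);
        p[i] = c2v[i] * rhox[i];
      }
    }

    if (n % record_every == 0) {
      int r = n / record_every;
      for (int s = 0; s < ns; ++s) out(r, s) = p[sensor_idx[s]];
    }
    if (n % 512 == 0) Rcpp::checkUserInterrupt();
  }

  fftw_destroy_plan(fwd); fftw_destroy_plan(bwd);
  fftw_destroy_plan(fwd2); fftw_destroy_plan(bwd2);
  return out;
}
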