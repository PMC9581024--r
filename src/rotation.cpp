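// Axis-angle rotations, their Jacobians, and the rotate-then-project-z map
// used by both the simulator and the fitting loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat33 skew(const arma::vec3& w) {
  arma::mat33 K;
  K(0,0)=0;      K(0,1)=-w(2); K(0,2)= w(1);
  K(1,0)= w(2);  K(1,1)=0;     K(1,2)=-w(0);
  K(2,0)=-w(1);  K(2,1)= w(0); K(2,2)=0;
  return K;
}

static arma::mat33 aa_to_mat(const arma::vec3& w) {
  double th = arma::norm(w);
  arma::mat33 I = arma::eye(3,3);
  arma::mat33 K = skew(w);
  double a, b;  // R = I + a K + b K^2 with series-safe coefficients
  if (th < 1e-8) {
    a = 1.0 - th*th/6.0;
    b = 0.5 - th*th/24.0;
  } else {
    a = std::sin(th)/th;
    b = (1.0 - std::cos(th))/(th*th);
  }
  return I + a*K + b*(K*K);
}

// [[Rcpp::export]]
arma::mat cpp_axis_angle_to_matrix(const arma::vec& rot) {
  return aa_to_mat(arma::vec3(rot));
}

// dR/dw_i stacked as a 9x3 matrix (column i = vec(dR/dw_i), column-major).
// Closed form of Gallego & Yezzi; small-angle limit dR/dw_i = [e_i]_x.
// [[Rcpp::export]]
arma::mat cpp_rotation_jacobian(const arma::vec& rot) {
  arma::vec3 w(rot);
  double th = arma::norm(w);
  arma::mat33 R = aa_to_mat(w);
  arma::mat J(9, 3);
  for (int i = 0; i < 3; ++i) {
    arma::vec3 e = arma::zeros<arma::vec>(3);
    e(i) = 1.0;
    arma::mat33 dR;
    if (th < 1e-6) {
      dR = skew(e);
    } else {
      arma::vec3 v = arma::cross(w, (arma::eye(3,3) - R) * e);
      dR = ((w(i) * skew(w) + skew(v)) / (th*th)) * R;
    }
    J.col(i) = arma::vectorise(dR);
  }
  return J;
}

// Rotate 3D vertices, drop z, translate in-plane: P = (R V^T)_{xy}^T + t.
// [[Rcpp::export]]
arma::mat cpp_transform_project(const arma::mat& V, const arma::vec& rot,
                                const arma::vec& trans) {
  arma::mat33 R = aa_to_mat(arma::vec3(rot));
  arma::mat RV = V * R.t();           // N x 3
  arma::mat P = RV.cols(0, 1);
  P.col(0) += trans(0);
  P.col(1) += trans(1);
  return P;
}

// Backward pass of cpp_transform_project.
// dP: N x 2 upstream gradient. Returns dV (N x 3), drot (3), dtrans (2).
// [[Rcpp::export]]
List cpp_transform_project_backward(const arma::mat& V, const arma::vec& rot,
                                    const arma::mat& dP) {
  arma::mat33 R = aa_to_mat(arma::vec3(rot));
  arma::mat J = cpp_rotation_jacobian(rot);  // 9 x 3
  // dV = dP * R[0:1, ] (rows x,y of R)
  arma::mat Rxy = R.rows(0, 1);              // 2 x 3
  arma::mat dV = dP * Rxy;                   // N x 3
  arma::vec drot(3, arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    arma::mat33 dR;
    dR = arma::reshape(J.col(i), 3, 3);
    arma::mat dRV = V * dR.t();              // N x 3
    drot(i) = arma::accu(dP % dRV.cols(0, 1));
  }
  arma::vec dtrans(2);
  dtrans(0) = arma::accu(dP.col(0));
  dtrans(1) = arma::accu(dP.col(1));
  return List::create(_["dV"] = dV, _["drot"] = drot, _["dtrans"] = dtrans);
}
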