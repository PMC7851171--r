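# Daubechies-38 orthonormal scaling filter (76 taps). Tabulated standard
# wavelet filter-bank coefficients; the highpass filter follows from the
# quadrature-mirror relation g[n] = (-1)^n h[L-1-n].
.db38_lo <- c(
  -1.71615245108874421e-18, 4.30459683955879032e-17, -4.40530704248346116e-16,
    2.04509967678898872e-15, -4.56339716212737354e-16, -4.24981781957146316e-14,
    1.80866123627453061e-13, 2.62649650406525195e-14, -2.48478923756364274e-12,
    6.29153731703950837e-12, 1.10169293459945451e-11, -8.27825652253813440e-11,
    6.73233649018930873e-11, 5.26113255735759866e-10, -1.34919775398344888e-09,
    -1.43632948779513575e-09, 1.03470453927485852e-08, -5.42427480028729824e-09,
    -4.88475793745928662e-08, 8.40035104689596572e-08, 1.39637754550835535e-07,
    -5.18773373887414488e-07, -8.48708758607259257e-08, 2.14996026993966525e-06,
    -1.55084435011860260e-06, -6.45673042846961899e-06, 1.03735918404559978e-05,
    1.33417614992135041e-05, -4.17514164854039790e-05, -1.15540910383371724e-05,
    1.26204335016617082e-04, -4.55568269666841997e-05, -3.03102046072661175e-04,
    2.81763925038067066e-04, 5.81075975053286392e-04, -9.42461407722737748e-04,
    -8.44862666553777494e-04, 2.40069778189097322e-03, 7.16982182106401912e-04,
    -5.07131450921834842e-03, 5.62571574840353152e-04, 9.21478503219718033e-03,
    -4.13130665603108922e-03, -1.47018820653986824e-02, 1.12904972786859650e-02,
    2.09046452556552430e-02, -2.31141340205493172e-02, -2.68914938808945160e-02,
    4.00549811051159471e-02, 3.19898775315378067e-02, -6.17662087084131575e-02,
    -3.66051034028742964e-02, 8.72043982620397534e-02, 4.30958954330476415e-02,
    -1.14731170710744373e-01, -5.65864586307273792e-02, 1.41414734073382675e-01,
    8.56381215561510534e-02, -1.59912565158244369e-01, -1.41795685973059610e-01,
    1.49985119618717022e-01, 2.32125963835353111e-01, -6.22665060478243201e-02,
    -3.21675637808997883e-01, -1.82867667708335901e-01, 2.13050571355578505e-01,
    4.93356078517100782e-01, 4.96591175311718092e-01, 3.30775781411014658e-01,
    1.60071993564110698e-01, 5.78899436128592557e-02, 1.56372493475721575e-02,
    3.08308811925375173e-03, 4.21170266472711634e-04, 3.57625199426402332e-05,
    1.42577664167413176e-06
)

.db38_hi <- (-1)^(0:(length(.db38_lo) - 1)) * rev(.db38_lo)
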