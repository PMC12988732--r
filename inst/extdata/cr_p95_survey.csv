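area,metal,group,cr
GY,Cr,male,4.2e-5
GY,Cr,female,6.3e-6
GY,Cr,child,5.6e-5
GY,Cd,male,1.7e-5
GY,Cd,female,5.4e-6
GY,Cd,child,2.1e-5
GY,Pb,male,5.0e-8
GY,Pb,female,1.4e-8
GY,Pb,child,1.7e-7
WC,Cr,male,2.0e-5
WC,Cr,female,2.3e-5
WC,Cr,child,7.7e-5
WC,Cd,male,5.0e-6
WC,Cd,female,4.7e-7
WC,Cd,child,2.0e-5
WC,Pb,male,5.9e-8
WC,Pb,female,3.5e-6
WC,Pb,child,2.3e-7
DG-F,Cr,male,4.7e-5
DG-F,Cr,female,5.5e-5
DG-F,Cr,child,1.9e-4
DG-F,Cd,male,1.3e-6
DG-F,Cd,female,1.5e-6
DG-F,Cd,child,5.0e-6
DG-F,Pb,male,5.0e-8
DG-F,Pb,female,5.9e-8
DG-F,Pb,child,2.0e-7
XY,Cr,male,1.8e-5
XY,Cr,female,2.2e-5
XY,Cr,child,7.2e-5
XY,Cd,male,7.6e-6
XY,Cd,female,7.1e-7
XY,Cd,child,3.0e-5
XY,Pb,male,5.8e-8
XY,Pb,female,3.9e-6
XY,Pb,child,2.3e-7
GZ-C,Cr,male,1.7e-5
GZ-C,Cr,female,2.0e-5
GZ-C,Cr,child,7.2e-5
GZ-C,Cd,male,8.4e-6
GZ-C,Cd,female,1.0e-5
GZ-C,Cd,child,3.5e-5
GZ-C,Pb,male,4.9e-8
GZ-C,Pb,female,5.8e-8
GZ-C,Pb,child,2.0e-7
SJZ-C,Cr,male,2.8e-5
SJZ-C,Cr,female,3.3e-5
SJZ-C,Cr,child,9.8e-5
SJZ-C,Cd,male,7.6e-6
SJZ-C,Cd,female,9.0e-6
SJZ-C,Cd,child,3.0e-5
SJZ-C,Pb,male,5.4e-8
SJZ-C,Pb,female,6.4e-8
SJZ-C,Pb,child,2.1e-7
SJZ-F,Cr,male,5.1e-5
SJZ-F,Cr,female,6.0e-5
SJZ-F,Cr,child,2.0e-4
SJZ-F,Cd,male,1.3e-6
SJZ-F,Cd,female,1.5e-6
SJZ-F,Cd,child,4.9e-6
SJZ-F,Pb,male,5.9e-8
SJZ-F,Pb,female,7.0e-8
SJZ-F,Pb,child,2.4e-7
DZ,Cr,male,2.5e-5
DZ,Cr,female,2.9e-5
DZ,Cr,child,1.0e-4
DZ,Cd,male,6.8e-6
DZ,Cd,female,9.6e-5
DZ,Cd,child,2.8e-5
DZ,Pb,male,1.0e-7
DZ,Pb,female,1.2e-6
DZ,Pb,child,4.2e-7
EM,Cr,male,3.3e-5
EM,Cr,female,3.9e-5
EM,Cr,child,1.3e-4
EM,Cd,male,7.7e-6
EM,Cd,female,7.2e-7
EM,Cd,child,3.0e-5
EM,Pb,male,7.9e-8
EM,Pb,female,4.7e-6
EM,Pb,child,3.1e-7
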