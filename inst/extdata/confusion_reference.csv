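pretreatment,validation,model,actual,O,R,U,ca_reported
snv1d,cv,svm,O,36,15,0,88.2
snv1d,cv,svm,R,13,54,0,88.2
snv1d,cv,svm,U,0,0,120,88.2
snv1d,cv,knn,O,28,23,0,80.7
snv1d,cv,knn,R,23,44,0,80.7
snv1d,cv,knn,U,0,0,120,80.7
snv1d,cv,nn,O,39,12,0,88.7
snv1d,cv,nn,R,15,52,0,88.7
snv1d,cv,nn,U,0,0,120,88.7
snv1d,cv,nb,O,32,19,0,80.7
snv1d,cv,nb,R,26,41,0,80.7
snv1d,cv,nb,U,0,1,119,80.7
snv1d,cv,lda,O,35,16,0,84.0
snv1d,cv,lda,R,20,46,1,84.0
snv1d,cv,lda,U,0,1,119,84.0
snv1d,test,svm,O,9,3,0,84.7
snv1d,test,svm,R,6,10,0,84.7
snv1d,test,svm,U,0,0,31,84.7
snv1d,test,knn,O,9,3,0,84.7
snv1d,test,knn,R,6,10,0,84.7
snv1d,test,knn,U,0,0,31,84.7
snv1d,test,nn,O,10,2,0,91.5
snv1d,test,nn,R,3,13,0,91.5
snv1d,test,nn,U,0,0,31,91.5
snv1d,test,nb,O,7,5,0,79.7
snv1d,test,nb,R,7,9,0,79.7
snv1d,test,nb,U,0,0,31,79.7
snv1d,test,lda,O,6,6,0,81.4
snv1d,test,lda,R,4,12,0,81.4
snv1d,test,lda,U,0,1,30,81.4
msc2d,cv,svm,O,36,15,0,87.4
msc2d,cv,svm,R,15,52,0,87.4
msc2d,cv,svm,U,0,0,120,87.4
msc2d,cv,knn,O,32,19,0,83.2
msc2d,cv,knn,R,21,46,0,83.2
msc2d,cv,knn,U,0,0,120,83.2
msc2d,cv,nn,O,34,17,0,85.3
msc2d,cv,nn,R,16,51,0,85.3
msc2d,cv,nn,U,1,1,118,85.3
msc2d,cv,nb,O,24,27,0,79.4
msc2d,cv,nb,R,22,45,0,79.4
msc2d,cv,nb,U,0,0,120,79.4
msc2d,cv,lda,O,31,20,0,81.1
msc2d,cv,lda,R,21,45,1,81.1
msc2d,cv,lda,U,1,2,117,81.1
msc2d,test,svm,O,10,3,0,89.8
msc2d,test,svm,R,3,13,0,89.8
msc2d,test,svm,U,0,0,30,89.8
msc2d,test,knn,O,9,4,0,86.4
msc2d,test,knn,R,4,12,0,86.4
msc2d,test,knn,U,0,0,30,86.4
msc2d,test,nn,O,8,5,0,84.7
msc2d,test,nn,R,4,12,0,84.7
msc2d,test,nn,U,0,0,30,84.7
msc2d,test,nb,O,5,7,1,78.0
msc2d,test,nb,R,3,11,2,78.0
msc2d,test,nb,U,0,0,30,78.0
msc2d,test,lda,O,4,9,0,76.3
msc2d,test,lda,R,5,11,0,76.3
msc2d,test,lda,U,0,0,30,76.3
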